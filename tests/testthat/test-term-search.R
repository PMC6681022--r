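test_that("hits use case-insensitive literal substring semantics", {
  corpus <- make_corpus(
    make_record(examination_text = "Microchipped today under GA"),
    make_record(patient_id = "P2", examination_text = "microcytic anaemia"),
    make_record(patient_id = "P3", examination_text = "micro chip implanted"),
    make_record(patient_id = "P4", examination_text = "nothing relevant")
  )
  expect_setequal(find_hits(corpus, "microc")$record_refs, c(1, 2))
  expect_equal(find_hits(corpus, "micro c")$record_refs, 3)
  expect_equal(find_hits(corpus, "MICROC")$record_refs, c(1, 2))
  expect_error(find_hits(corpus, ""), "non-empty")
})

test_that("patient IDs in a hit set never exceed its record count", {
  sim <- generate_corpus(generator_config(n_patients = 500, seed = 8))
  for (term in c("microc", "implant", "m/c", "mchip")) {
    h <- find_hits(sim$corpus, term)
    expect_lte(length(h$patient_ids), length(h$record_refs))
  }
})

test_that("term ranking matches an independent brute-force scan", {
  sim <- generate_corpus(generator_config(n_patients = 800, seed = 1))
  corpus <- sim$corpus
  terms <- c("implant", "mchip", "m chip", "microc", "m/c", "micro-c", "micro c")
  ranking <- rank_terms(corpus, terms, reference = "microc")

  # oracle: plain grepl over lowercased text, term by term
  oracle <- lapply(terms, function(tm) {
    which(vapply(corpus$examination_text,
                 function(x) grepl(tm, tolower(x), fixed = TRUE),
                 logical(1), USE.NAMES = FALSE))
  })
  names(oracle) <- terms
  ref_pat <- unique(corpus$patient_id[oracle[["microc"]]])
  for (i in seq_len(nrow(ranking))) {
    tm <- ranking$term[i]
    expect_equal(ranking$n_records[i], length(oracle[[tm]]))
    expect_equal(ranking$n_patients[i], length(unique(corpus$patient_id[oracle[[tm]]])))
    if (tm != "microc") {
      expect_equal(ranking$n_patients_shared_with_reference[i],
                   length(intersect(unique(corpus$patient_id[oracle[[tm]]]), ref_pat)))
    }
  }
  expect_equal(ranking$n_records, sort(ranking$n_records, decreasing = TRUE))
  expect_equal(ranking$term[1], "microc")
  expect_true(is.na(ranking$n_patients_shared_with_reference[ranking$term == "microc"]))
})

test_that("tied terms are ordered lexicographically", {
  corpus <- make_corpus(
    make_record(examination_text = "zzz here"),
    make_record(patient_id = "P2", examination_text = "aaa here")
  )
  ranking <- rank_terms(corpus, c("zzz", "aaa"), reference = "aaa")
  expect_equal(ranking$term, c("aaa", "zzz"))
  expect_error(rank_terms(corpus, character(0), "x"), "at least one")
  expect_error(rank_terms(corpus, c("aaa"), "bbb"), "reference")
})

test_that("narrowing a term can only shrink the hit set", {
  sim <- generate_corpus(generator_config(n_patients = 1500, seed = 21))
  broad <- find_hits(sim$corpus, "microc")
  narrow <- find_hits(sim$corpus, "microch")
  expect_true(all(narrow$record_refs %in% broad$record_refs))
  # general: s a substring of t implies hits(t) subset of hits(s)
  pairs <- list(c("micro", "microc"), c("chip", "microchip"), c("m/c", "m/c "))
  for (p in pairs) {
    hs <- find_hits(sim$corpus, p[1])
    ht <- find_hits(sim$corpus, p[2])
    expect_true(all(ht$record_refs %in% hs$record_refs))
  }
})

test_that("differential words extract the maximal token at the match", {
  corpus <- make_corpus(
    make_record(examination_text = "moderate Microcytosis noted"),
    make_record(patient_id = "P2", examination_text = "microcip implanted today"),
    make_record(patient_id = "P3",
                examination_text = "microchip implanted; bloods show microcytic cells"),
    make_record(patient_id = "P4", examination_text = "microchip implanted")
  )
  words <- differential_words(corpus, "microc", "microch")
  expect_equal(words$token, c("microcip", "microcytosis"))
  expect_equal(words$count, c(1L, 1L))
})

test_that("differential word counts conserve the record-set difference", {
  sim <- generate_corpus(generator_config(n_patients = 3000, confounder_rate = 0.01,
                                          seed = 13))
  words <- differential_words(sim$corpus, "microc", "microch")
  nb <- length(find_hits(sim$corpus, "microc")$record_refs)
  nn <- length(find_hits(sim$corpus, "microch")$record_refs)
  expect_equal(sum(words$count), nb - nn)
  expect_true(all(grepl("microc", words$token, fixed = TRUE)))
  expect_false(any(grepl("microch", words$token, fixed = TRUE)))
})

test_that("inconsistent broad/narrow pairs are rejected", {
  corpus <- make_corpus(
    make_record(examination_text = "microchip implanted"),
    make_record(patient_id = "P2", examination_text = "nail trim only")
  )
  expect_error(differential_words(corpus, "microc", "nail"), "subset")
})
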