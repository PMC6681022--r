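test_that("representative texts route to the expected categories", {
  cases <- list(
    c("microchip implanted 956000012345678, batch sticker attached",
      "implantation_event"),
    c("Weight: __ Microchip: __ Vacc: __", "blank_prepopulated_form"),
    c("owner declined microchipping at this time", "owner_refusal"),
    c("microcytic hypochromic anaemia", "other_word_or_typo"),
    c("scanned on admission, no microchip found", "absence_noted"),
    c("already microchipped, number on file", "preexisting_chip_confirmation"),
    c("completely unrelated text", "none_of_the_above")
  )
  for (case in cases) {
    rec <- make_record(examination_text = case[1])
    expect_equal(classify_hit(rec), case[2], label = case[1])
  }
})

test_that("every generator template is recovered by its own rule", {
  # zero-noise construction guarantee: rendered text always triggers its
  # own category's rule, for every template of every category
  set.seed(99)
  for (category in hit_categories()) {
    for (i in 1:12) {
      txt <- render_text(category, chip = "956000012345678")
      rec <- make_record(examination_text = txt)
      expect_equal(classify_hit(rec), category, label = txt)
    }
  }
  for (i in 1:6) {
    txt <- render_text("implantation_event", litter = TRUE)
    expect_equal(classify_hit(make_record(examination_text = txt)),
                 "implantation_event", label = txt)
    expect_true(detect_litter(make_record(examination_text = txt,
                                          is_litter_record = FALSE)))
  }
})

test_that("rule sets round-trip through YAML preserving order", {
  rules <- default_rules()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_rules(rules, path)
  expect_identical(read_rules(path), rules)
  expect_error(write_rules(tibble::tibble(pattern = "x", category = "bogus"),
                           path), "Unknown categories")
})

test_that("hit sampling is reproducible, exhaustive and uniform", {
  corpus <- make_corpus(lapply(1:10, function(i) {
    make_record(patient_id = sprintf("P%02d", i),
                examination_text = "microchip implanted")
  }))
  hits <- find_hits(corpus, "microc")

  full <- sample_hits(hits, 10, seed = 4)
  expect_setequal(full, hits$record_refs)
  expect_identical(sample_hits(hits, 5, seed = 7), sample_hits(hits, 5, seed = 7))
  expect_error(sample_hits(hits, 11, seed = 1), "Cannot sample")

  # frequency of one fixed record over repeated single draws
  draws <- vapply(1:10000, function(s) sample_hits(hits, 1, seed = s), integer(1))
  freq <- mean(draws == 3L)
  expect_lt(abs(freq - 0.1), 3 * sqrt(0.1 * 0.9 / 10000))
})

test_that("litter detection uses the flag or the text", {
  expect_true(detect_litter(make_record(is_litter_record = TRUE,
                                        examination_text = "microchip implanted")))
  expect_true(detect_litter(make_record(
    examination_text = "litter of 6 pups all microchipped")))
  expect_false(detect_litter(make_record(
    examination_text = "microchip implanted at vacc")))
})

test_that("concurrent interactions are extracted from implantation text", {
  grab <- function(txt) extract_concurrent(make_record(examination_text = txt))[[1]]
  expect_equal(grab("C5 vaccination given, microchip implanted"), "vaccination")
  expect_equal(grab("spay + microchip under same GA"), "spay")
  expect_equal(grab("microchip implanted, no other procedures"), "none")
  expect_setequal(grab("castration and C3 vaccination; microchip implanted"),
                  c("vaccination", "castration"))
})

test_that("classification tables conserve their sample size", {
  tbl <- tabulate_classifications(rep("implantation_event", 3))
  expect_equal(tbl$count[tbl$category == "implantation_event"], 3)
  expect_equal(sum(tbl$count), 3)
  expect_equal(attr(tbl, "total"), 3)

  empty <- tabulate_classifications(character(0))
  expect_equal(sum(empty$count), 0)
  expect_equal(nrow(empty), 17)
  expect_error(tabulate_classifications("nonsense"), "Unknown categories")

  # pass-through of generator ground-truth labels
  sim <- generate_corpus(generator_config(n_patients = 1000, seed = 7))
  truth <- hit_truth(sim)$category
  tbl <- tabulate_classifications(truth)
  expect_equal(sum(tbl$count), length(truth))
  expect_equal(tbl$count[tbl$category == "implantation_event"],
               sum(truth == "implantation_event"))
})

test_that("the classifier recovers ground truth on a noisy corpus", {
  sim <- generate_corpus(generator_config(n_patients = 2000, seed = 31))
  ht <- hit_truth(sim)
  pred <- classify_hits(ht$records)
  expect_gte(mean(pred == ht$category), 0.95)

  clean <- generate_corpus(generator_config(n_patients = 1500, seed = 32,
                                            typo_rate = 0, confounder_rate = 0,
                                            alt_term_rate = 0))
  ht0 <- hit_truth(clean)
  expect_equal(mean(classify_hits(ht0$records) == ht0$category), 1)
})
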