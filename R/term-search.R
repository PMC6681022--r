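#' Find records containing a search term
#'
#' Case-insensitive literal substring search over the free-text examination
#' field. There is no tokenization: the term "microc" matches "microchip",
#' "microcytic" and any other word containing the string, which is exactly
#' why hit classification is needed downstream.
#'
#' @param corpus A corpus tibble.
#' @param term Non-empty search string, matched literally (spaces included).
#' @return A list of class `hit_set` with elements `term`, `record_refs`
#'   (record IDs of matching rows) and `patient_ids` (unique patients among
#'   them).
#' @export
#' @examples
#' corpus <- generate_corpus(generator_config(n_patients = 50, seed = 1))$corpus
#' find_hits(corpus, "microc")
find_hits <- function(corpus, term) {
  if (!is.character(term) || length(term) != 1 || is.na(term) || nchar(term) == 0) {
    abort("`term` must be a single non-empty string.")
  }
  hit <- stringr::str_detect(corpus$examination_text, stringr::fixed(term, ignore_case = TRUE))
  hit[is.na(hit)] <- FALSE
  structure(
    list(
      term = term,
      record_refs = corpus$record_id[hit],
      patient_ids = unique(corpus$patient_id[hit])
    ),
    class = "hit_set"
  )
}

#' @export
print.hit_set <- function(x, ...) {
  cat(sprintf("<hit_set> term '%s': %d records, %d unique patients\n",
              x$term, length(x$record_refs), length(x$patient_ids)))
  invisible(x)
}

#' Rank search terms by the number of records they return
#'
#' Each candidate term is searched independently; terms are ordered by
#' record count (descending, ties broken alphabetically), and for every
#' non-reference term the number of its patients also found by the
#' reference term is reported. The top-ranked term is the natural choice of
#' primary search ("Search A").
#'
#' @param corpus A corpus tibble.
#' @param terms Character vector of candidate search terms.
#' @param reference One of `terms`; overlap counts are computed against its
#'   hit set.
#' @return A tibble with columns `term`, `n_records`, `n_patients`,
#'   `n_patients_shared_with_reference` (`NA` for the reference row),
#'   ordered by `n_records` descending.
#' @export
rank_terms <- function(corpus, terms, reference) {
  if (length(terms) == 0) abort("`terms` must contain at least one term.")
  if (!reference %in% terms) abort("`reference` must be one of `terms`.")
  hits <- lapply(terms, function(t) find_hits(corpus, t))
  names(hits) <- terms
  ref_patients <- hits[[reference]]$patient_ids
  rows <- tibble::tibble(
    term = terms,
    n_records = vapply(hits, function(h) length(h$record_refs), integer(1),
                       USE.NAMES = FALSE),
    n_patients = vapply(hits, function(h) length(h$patient_ids), integer(1),
                        USE.NAMES = FALSE),
    n_patients_shared_with_reference = vapply(hits, function(h) {
      if (identical(h$term, reference)) NA_integer_
      else length(intersect(h$patient_ids, ref_patients))
    }, integer(1), USE.NAMES = FALSE)
  )
  rows[order(-rows$n_records, rows$term), , drop = FALSE]
}

#' Words found by a broad term but not a narrow one
#'
#' For each record hit by `broad` but not by `narrow`, the maximal
#' alphabetic token containing the first broad-term match is extracted and
#' lowercased, and one count per record is recorded. This is how one
#' decides whether narrowing a search (say from "microc" to "microch")
#' would lose genuine records (misspellings of "microchip") or only
#' confounders ("microcytic", "microconvex", ...).
#'
#' `narrow`'s hit set must be a subset of `broad`'s; this holds whenever
#' `broad` is a substring of `narrow`, and is verified at run time.
#'
#' @param corpus A corpus tibble.
#' @param broad,narrow Search terms.
#' @return A tibble with columns `token` and `count`, sorted alphabetically
#'   by token. Counts sum to the number of records hit by `broad` only.
#' @export
differential_words <- function(corpus, broad, narrow) {
  hb <- find_hits(corpus, broad)
  hn <- find_hits(corpus, narrow)
  if (!all(hn$record_refs %in% hb$record_refs)) {
    abort(sprintf("Hits of '%s' are not a subset of hits of '%s'; differential words are undefined.",
                  narrow, broad))
  }
  only <- setdiff(hb$record_refs, hn$record_refs)
  if (length(only) == 0) {
    return(tibble::tibble(token = character(0), count = integer(0)))
  }
  texts <- corpus$examination_text[match(only, corpus$record_id)]
  tokens <- vapply(texts, function(txt) {
    low <- tolower(txt)
    pos <- stringr::str_locate(low, stringr::fixed(tolower(broad)))[1, ]
    # expand the match to the maximal run of letters around it
    chars <- strsplit(low, "")[[1]]
    is_alpha <- grepl("[a-z]", chars)
    start <- pos[["start"]]
    end <- pos[["end"]]
    while (start > 1 && is_alpha[start - 1]) start <- start - 1
    while (end < length(chars) && is_alpha[end + 1]) end <- end + 1
    substr(low, start, end)
  }, character(1), USE.NAMES = FALSE)
  out <- tibble::as_tibble(table(token = tokens))
  names(out)[2] <- "count"
  out$count <- as.integer(out$count)
  out[order(out$token), , drop = FALSE]
}
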