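confounder_words <- c(
  "microcardia", "microcautery", "microcilia", "microclimate", "microclone",
  "microclot", "microconidia", "microconvex", "microcrystals", "microcysts",
  "microcytes", "microcytic", "microcytosis", "microcope"
)

#' Default hit-classification rules
#'
#' An ordered table of regular-expression patterns, each mapped to one of
#' the 17 hit categories. Classification is first-match-wins, so rule order
#' is part of the configuration: specific situations (a complication at the
#' implantation site, an owner refusing) are listed before the generic
#' implantation and confirmation rules they would otherwise fall into. A
#' hit matching no rule gets the default category `none_of_the_above`.
#'
#' Patterns are matched case-insensitively against the full examination
#' text. The set replaces, for synthetic and rule-describable corpora, the
#' manual chart review that produced the original taxonomy; it can be
#' edited, re-ordered, serialized with [write_rules()] and reloaded with
#' [read_rules()].
#'
#' @return A tibble with columns `pattern` and `category`, in priority order.
#' @export
default_rules <- function() {
  tibble::tribble(
    ~pattern, ~category,
    "microchip:?\\s*_+", "blank_prepopulated_form",
    "(swelling|swollen|abscess|infection|migrat)[^.]*(microchip|chip site)|microchip[^.]*(swelling|swollen|abscess|infection|migrat|complication)",
      "implantation_complication",
    "(owner|client)[^.]*(declined|refused|refuses)[^.]*microchip", "owner_refusal",
    "plan to microchip|microchip at (the )?next|schedule[d]?( for)? microchip|microchip (due|scheduled|booked)|to be microchipped",
      "future_plan",
    "reported lost|missing since", "reported_lost",
    "stray[^.]*owner (identified|contacted|located)|owner (identified|contacted|located)[^.]*stray",
      "stray_id_successful",
    "stray[^.]*(unable to (identify|contact)|not registered|no owner details|no microchip)",
      "stray_id_attempted",
    "travel certificate|export (paperwork|certificate)|import permit", "travel_requirements",
    "microchip[^.]*(failed to (scan|read)|not reading|faulty|unreadable)|(faulty|unreadable) microchip",
      "technical_problem",
    "previous (owner|vet)|prior (owner|clinic)", "contact_previous_owner",
    "change of (ownership|details|address)|transfer of (ownership|registration)",
      "admin_assistance",
    "microchip number[^.]*(for (clinic|our) records|to be (collected|recorded))|collect microchip number",
      "internal_number_request",
    "no microchip (found|detected|present)|microchip not found|not microchipped|scanned[^.]*no (micro)?chip",
      "absence_noted",
    "microchip (scanned and |number )?(confirmed|verified|on file)|already microchipped|existing microchip|microchip present",
      "preexisting_chip_confirmation",
    "microchip(ped)? implanted|implanted (a )?microchip|microchipped (today|under|at|and)|microchip (inserted|placed|given)|all microchipped",
      "implantation_event",
    paste0("\\b(", paste(confounder_words, collapse = "|"), "|microcip)"),
      "other_word_or_typo"
  )
}

check_rules <- function(rules) {
  if (!all(c("pattern", "category") %in% names(rules))) {
    abort("A rule set needs `pattern` and `category` columns.")
  }
  bad <- setdiff(rules$category, hit_categories())
  if (length(bad) > 0) {
    abort(sprintf("Unknown categories in rule set: %s.", paste(bad, collapse = ", ")))
  }
  rules
}

#' Serialize / load a rule set
#'
#' Rules are stored as an ordered YAML list of `pattern`/`category` pairs,
#' so the exact configuration used for a classification can be shipped with
#' its results.
#'
#' @param rules A rule tibble (see [default_rules()]).
#' @param path File path.
#' @return `write_rules()` returns `path` invisibly; `read_rules()` returns
#'   the rule tibble in file order.
#' @export
write_rules <- function(rules, path) {
  check_rules(rules)
  yaml::write_yaml(purrr::pmap(rules, function(pattern, category) {
    list(pattern = pattern, category = category)
  }), path)
  invisible(path)
}

#' @rdname write_rules
#' @export
read_rules <- function(path) {
  raw <- yaml::read_yaml(path)
  check_rules(tibble::tibble(
    pattern = vapply(raw, `[[`, character(1), "pattern"),
    category = vapply(raw, `[[`, character(1), "category")
  ))
}

#' Classify examination texts into hit categories
#'
#' Applies an ordered rule set (first matching pattern wins,
#' case-insensitive) to each text; texts matching no rule get
#' `none_of_the_above`. `classify_hits()` is the vectorised workhorse over
#' a corpus; `classify_hit()` classifies a single record.
#'
#' @param corpus A corpus tibble (records assumed to be hits of the active
#'   search term).
#' @param rules A rule tibble; defaults to [default_rules()].
#' @return `classify_hits()`: character vector of categories, one per row
#'   of `corpus`. `classify_hit()`: a single category.
#' @export
classify_hits <- function(corpus, rules = default_rules()) {
  check_rules(rules)
  texts <- corpus$examination_text
  out <- rep("none_of_the_above", length(texts))
  undecided <- rep(TRUE, length(texts))
  for (i in seq_len(nrow(rules))) {
    if (!any(undecided)) break
    m <- stringr::str_detect(
      texts[undecided],
      stringr::regex(rules$pattern[i], ignore_case = TRUE)
    )
    m[is.na(m)] <- FALSE
    idx <- which(undecided)[m]
    out[idx] <- rules$category[i]
    undecided[idx] <- FALSE
  }
  out
}

#' @rdname classify_hits
#' @param record A one-row corpus tibble.
#' @export
classify_hit <- function(record, rules = default_rules()) {
  classify_hits(record[1, , drop = FALSE], rules)
}

#' Randomly sample hits for review
#'
#' Uniform sampling without replacement, reproducible given a seed; the
#' analogue of drawing a fixed-size random sample of search results for
#' manual chart review.
#'
#' @param hits A `hit_set` from [find_hits()].
#' @param n Sample size, at most the number of hit records.
#' @param seed Integer seed.
#' @return Integer vector of `n` sampled record IDs.
#' @export
sample_hits <- function(hits, n, seed) {
  pool <- hits$record_refs
  if (n > length(pool)) {
    abort(sprintf("Cannot sample %d from %d hits.", n, length(pool)))
  }
  with_local_seed(seed, pool[sample.int(length(pool), n)])
}

litter_pattern <- "litter of|pups all|kittens all|dam's record|whole litter|group litter"

#' Detect litter implantation events
#'
#' An implantation is a litter event when it was recorded in the dam's EPR
#' or under a group patient ID covering the whole litter, rather than on an
#' individual animal's record. Detection uses the structured
#' `is_litter_record` flag when set, and a litter text pattern otherwise.
#'
#' @param records A corpus tibble of records classified as implantation
#'   events.
#' @return Logical vector, one element per row.
#' @export
detect_litter <- function(records) {
  flag <- records$is_litter_record
  flag[is.na(flag)] <- FALSE
  flag | stringr::str_detect(records$examination_text,
                             stringr::regex(litter_pattern, ignore_case = TRUE))
}

concurrent_patterns <- c(
  vaccination = "vaccin|\\bc[35]\\b|\\bf[34]\\b|booster",
  spay = "spay|ovariohysterectomy",
  castration = "castrat",
  other_surgery = "lump removal|dental surgery|wound repair|surgery performed",
  other_consult = "recheck|consult"
)

#' Extract veterinary interactions concurrent with an implantation
#'
#' Scans the examination text of individual (non-litter) implantation
#' records for other interactions performed on the same visit. Returns
#' `"none"` when nothing else matches, so the result is never empty.
#'
#' @param records A corpus tibble of individual implantation records.
#' @return A list of character vectors, one per row, each a subset of
#'   [concurrent_classes()].
#' @export
extract_concurrent <- function(records) {
  lapply(records$examination_text, function(txt) {
    found <- names(concurrent_patterns)[vapply(concurrent_patterns, function(p) {
      isTRUE(stringr::str_detect(txt, stringr::regex(p, ignore_case = TRUE)))
    }, logical(1))]
    if (length(found) == 0) "none" else found
  })
}

#' Tabulate hit classifications
#'
#' Counts per category over all 17 classes (zeros included); counts always
#' sum to the number of labels supplied.
#'
#' @param labels Character vector of hit categories.
#' @return A tibble with columns `category` and `count`, one row per
#'   category in canonical order, plus a `total` attribute.
#' @export
tabulate_classifications <- function(labels) {
  bad <- setdiff(unique(labels), hit_categories())
  if (length(bad) > 0) {
    abort(sprintf("Unknown categories: %s.", paste(bad, collapse = ", ")))
  }
  counts <- table(factor(labels, levels = hit_categories()))
  out <- tibble::tibble(category = hit_categories(), count = as.integer(counts))
  attr(out, "total") <- length(labels)
  out
}
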