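concordance_classes <- c(
  "full_match", "breed_mismatch", "sex_mismatch", "breed_and_sex_mismatch",
  "species_mismatch"
)
# severity order, worst first, used to reduce multi-member groups
concordance_severity <- c(
  "species_mismatch", "breed_and_sex_mismatch", "sex_mismatch",
  "breed_mismatch", "full_match"
)

norm_breed <- function(x) {
  stringr::str_squish(tolower(dplyr::coalesce(x, "")))
}

#' Demographic concordance of two records sharing a chip
#'
#' A microchip is a permanent unique identifier, so two patient IDs with
#' the same chip number should describe the same animal. The pair is
#' classed by what disagrees: species (almost certainly a data-entry
#' error), both breed and sex, sex only, breed only, or nothing
#' (`full_match`, the same animal seen at multiple clinics). Breeds are
#' compared as exact text after lowercasing and whitespace collapse, so
#' near-misses like "Labrador" vs "Labrador cross" count as a breed
#' mismatch. The classification is symmetric in its arguments.
#'
#' @param rec_a,rec_b One-row corpus tibbles with the same chip value.
#' @return One of `"full_match"`, `"breed_mismatch"`, `"sex_mismatch"`,
#'   `"breed_and_sex_mismatch"`, `"species_mismatch"`.
#' @export
classify_pair <- function(rec_a, rec_b) {
  classify_pairs(
    rec_a$species, norm_breed(rec_a$breed), rec_a$sex,
    rec_b$species, norm_breed(rec_b$breed), rec_b$sex
  )
}

classify_pairs <- function(sp_a, br_a, sx_a, sp_b, br_b, sx_b) {
  dplyr::case_when(
    sp_a != sp_b ~ "species_mismatch",
    br_a != br_b & sx_a != sx_b ~ "breed_and_sex_mismatch",
    sx_a != sx_b ~ "sex_mismatch",
    br_a != br_b ~ "breed_mismatch",
    TRUE ~ "full_match"
  )
}

#' Group patient IDs sharing a microchip number
#'
#' Considers valid 15-digit chips only, takes one representative record per
#' patient ID (the earliest visit), and returns one group per chip value
#' held by two or more distinct patient IDs. Each group is classed by the
#' worst pairwise concordance among its members (severity: species >
#' breed-and-sex > sex > breed > full match).
#'
#' @param corpus A corpus tibble.
#' @return A tibble with one row per duplicate group: `chip`,
#'   `multiplicity` (number of distinct patient IDs), `concordance`, and
#'   `patient_ids` (comma-separated).
#' @export
group_by_chip <- function(corpus) {
  reps <- corpus[chip_is_valid(corpus$microchip), , drop = FALSE]
  if (nrow(reps) == 0) {
    return(tibble::tibble(chip = character(0), multiplicity = integer(0),
                          concordance = character(0), patient_ids = character(0)))
  }
  reps$microchip <- stringr::str_trim(reps$microchip)
  reps <- reps[order(reps$visit_date, reps$record_id), , drop = FALSE]
  reps <- reps[!duplicated(paste(reps$microchip, reps$patient_id)), , drop = FALSE]
  reps |>
    dplyr::group_by(chip = .data$microchip) |>
    dplyr::filter(dplyr::n() >= 2) |>
    dplyr::summarise(
      multiplicity = dplyr::n(),
      concordance = worst_pairwise(.data$species, norm_breed(.data$breed), .data$sex),
      patient_ids = paste(sort(.data$patient_id), collapse = ","),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$chip)
}

worst_pairwise <- function(species, breed, sex) {
  k <- length(species)
  if (k < 2) return(NA_character_)
  pairs <- utils::combn(k, 2)
  classes <- classify_pairs(
    species[pairs[1, ]], breed[pairs[1, ]], sex[pairs[1, ]],
    species[pairs[2, ]], breed[pairs[2, ]], sex[pairs[2, ]]
  )
  concordance_severity[min(match(classes, concordance_severity))]
}

#' Linkage report for duplicated microchip numbers
#'
#' Counts duplicate-chip groups by concordance class (with percentages of
#' all groups) and reports the multiplicity distribution. Class counts
#' partition the groups, so they always sum to the total.
#'
#' @param corpus A corpus tibble.
#' @return A list of class `linkage_report` with elements `groups` (the
#'   [group_by_chip()] table), `by_class` (tibble: `concordance`, `count`,
#'   `pct`), `multiplicity` (tibble: `multiplicity`, `count`), and
#'   `n_groups`.
#' @export
linkage_report <- function(corpus) {
  groups <- group_by_chip(corpus)
  n <- nrow(groups)
  counts <- table(factor(groups$concordance, levels = concordance_classes))
  by_class <- tibble::tibble(
    concordance = concordance_classes,
    count = as.integer(counts),
    pct = if (n > 0) 100 * as.integer(counts) / n else rep(NA_real_, length(counts))
  )
  mtab <- table(groups$multiplicity)
  mult <- tibble::tibble(
    multiplicity = as.integer(names(mtab)),
    count = as.integer(mtab)
  )
  structure(
    list(groups = groups, by_class = by_class, multiplicity = mult, n_groups = n),
    class = "linkage_report"
  )
}

#' @export
print.linkage_report <- function(x, ...) {
  cat(sprintf("<linkage_report> %d duplicate-chip groups\n", x$n_groups))
  print(x$by_class)
  invisible(x)
}
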