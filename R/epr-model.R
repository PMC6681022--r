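#' Validate a microchip field
#'
#' A valid Australian companion-animal microchip number is exactly 15
#' decimal digits. Anything else — too short, too long, containing
#' non-digit characters, or blank — is invalid. Blank, incomplete and
#' malformed fields are pooled as "invalid" downstream, but the reason is
#' retained. Leading and trailing whitespace is ignored; internal spaces or
#' punctuation make the field invalid.
#'
#' @param raw Character vector of microchip fields as entered (may contain
#'   `NA` or empty strings).
#' @return A tibble with one row per input and columns `status`
#'   (`"valid"`/`"invalid"`) and `reason`
#'   (`"ok"`, `"wrong_length"`, `"non_numeric"`, `"blank"`).
#' @export
#' @examples
#' validate_microchip(c("956000012345678", "95600001234567", "chip pending", ""))
validate_microchip <- function(raw) {
  x <- stringr::str_trim(as.character(raw))
  x[is.na(x)] <- ""
  reason <- dplyr::case_when(
    x == "" ~ "blank",
    stringr::str_detect(x, "[^0-9]") ~ "non_numeric",
    nchar(x) != 15L ~ "wrong_length",
    TRUE ~ "ok"
  )
  tibble::tibble(
    status = ifelse(reason == "ok", "valid", "invalid"),
    reason = reason
  )
}

#' Is a microchip field valid?
#'
#' @param raw Character vector of microchip fields.
#' @return Logical vector, `TRUE` where the field is a valid 15-digit number.
#' @export
chip_is_valid <- function(raw) {
  validate_microchip(raw)$status == "valid"
}

corpus_columns <- c(
  "patient_id", "clinic_id", "species", "breed", "sex", "date_of_birth",
  "microchip", "visit_date", "examination_text", "is_litter_record"
)

parse_date_column <- function(x, column) {
  x <- stringr::str_trim(as.character(x))
  x[!is.na(x) & x == ""] <- NA_character_
  out <- as.Date(rep(NA_character_, length(x)))
  present <- !is.na(x)
  if (any(present)) {
    parsed <- as.Date(x[present], format = "%Y-%m-%d")
    # as.Date() rolls some impossible dates over; require exact round-trip
    ok <- !is.na(parsed) & format(parsed, "%Y-%m-%d") == x[present]
    if (any(!ok)) {
      bad_row <- which(present)[which(!ok)[1]] + 1L  # header is file row 1
      abort(sprintf(
        "Unparseable date '%s' in column '%s' at file row %d (expected ISO-8601 YYYY-MM-DD).",
        x[present][which(!ok)[1]], column, bad_row
      ))
    }
    out[present] <- parsed
  }
  out
}

#' Read an EPR corpus from CSV
#'
#' One row per consultation line. Required columns: `patient_id`,
#' `clinic_id`, `species`, `breed`, `sex`, `date_of_birth`, `microchip`,
#' `visit_date`, `examination_text`, `is_litter_record`. Dates are
#' ISO-8601; missing dates and empty text become `NA`, not errors. A
#' `record_id` column is added (file row order) if not already present.
#'
#' @param path Path to a UTF-8 CSV file with a header row.
#' @return A tibble with one row per record.
#' @export
read_corpus <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  missing <- setdiff(corpus_columns, names(raw))
  if (length(missing) > 0) {
    abort(sprintf("Corpus file is missing mandatory column(s): %s.",
                  paste(missing, collapse = ", ")))
  }
  out <- tibble::tibble(
    record_id = if ("record_id" %in% names(raw)) as.integer(raw$record_id) else seq_len(nrow(raw)),
    patient_id = raw$patient_id,
    clinic_id = raw$clinic_id,
    species = raw$species,
    breed = raw$breed,
    sex = raw$sex,
    date_of_birth = parse_date_column(raw$date_of_birth, "date_of_birth"),
    microchip = dplyr::coalesce(raw$microchip, ""),
    visit_date = parse_date_column(raw$visit_date, "visit_date"),
    examination_text = dplyr::coalesce(raw$examination_text, ""),
    is_litter_record = tolower(dplyr::coalesce(raw$is_litter_record, "false")) %in%
      c("true", "t", "1", "yes")
  )
  bad_order <- !is.na(out$visit_date) & !is.na(out$date_of_birth) &
    out$visit_date < out$date_of_birth
  if (any(bad_order)) {
    abort(sprintf("visit_date precedes date_of_birth at file row %d.",
                  which(bad_order)[1] + 1L))
  }
  out
}

#' Write an EPR corpus to CSV
#'
#' Inverse of [read_corpus()]: a write/read round-trip is the identity on
#' all fields.
#'
#' @param corpus A corpus tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  out <- corpus
  out$date_of_birth <- format(out$date_of_birth, "%Y-%m-%d")
  out$visit_date <- format(out$visit_date, "%Y-%m-%d")
  out$is_litter_record <- ifelse(out$is_litter_record, "true", "false")
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}

#' Split a corpus into valid- and invalid-chip cohorts
#'
#' Every record is assigned to exactly one cohort by [validate_microchip()]
#' on its `microchip` field; the two cohorts partition the corpus.
#'
#' @param corpus A corpus tibble.
#' @return A list with elements `valid` and `invalid`, each a corpus tibble.
#' @export
split_cohorts <- function(corpus) {
  ok <- chip_is_valid(corpus$microchip)
  list(valid = corpus[ok, , drop = FALSE], invalid = corpus[!ok, , drop = FALSE])
}

#' Corpus-level counts
#'
#' Rows, unique patients, unique valid microchip numbers, and unique
#' patients by species. Unique chips are counted over valid 15-digit values
#' only; a chip shared by several patient IDs (the same animal seen at
#' multiple clinics) is counted once, so
#' `n_unique_patients - n_unique_chips` measures apparent multi-clinic
#' attendance in an all-valid corpus.
#'
#' @param corpus A corpus tibble.
#' @return A one-row tibble with columns `n_rows`, `n_unique_patients`,
#'   `n_unique_chips`, `n_dogs`, `n_cats`.
#' @export
count_corpus <- function(corpus) {
  patients <- corpus |>
    dplyr::distinct(.data$patient_id, .keep_all = TRUE)
  valid_chips <- corpus$microchip[chip_is_valid(corpus$microchip)]
  tibble::tibble(
    n_rows = nrow(corpus),
    n_unique_patients = nrow(patients),
    n_unique_chips = length(unique(stringr::str_trim(valid_chips))),
    n_dogs = sum(patients$species == "dog"),
    n_cats = sum(patients$species == "cat")
  )
}
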