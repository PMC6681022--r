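default_search_terms <- c("implant", "mchip", "m chip", "microc", "m/c",
                          "micro-c", "micro c")

#' Run the full implantation-event analysis
#'
#' Orchestrates the pipeline end to end: count the corpus, split it into
#' valid- and invalid-chip cohorts, rank the candidate search terms on the
#' valid cohort and adopt the top term as the primary search, draw an
#' independent random review sample of hits in each cohort (separate seeds
#' derived from the master seed), classify the samples with the rule set,
#' and compute the statistics: per-cohort PPV with a Yates chi-squared
#' comparison, litter-event comparison, Table-style per-category cohort
#' comparison, age-at-implantation summaries with a log-scale t-test of
#' dogs against cats, concurrent-interaction tabulation, broad-vs-narrow
#' differential words, duplicated-chip linkage, extrapolated event count,
#' and the fraction implanted within a legislative deadline.
#'
#' The report is reproducible bit-for-bit given (corpus, configuration,
#' seed), and every statistic is stored next to the inputs and convention
#' flags (Yates correction, denominators, quantile type, seeds) needed to
#' audit it.
#'
#' @param corpus A corpus tibble (from [read_corpus()] or
#'   [generate_corpus()]).
#' @param rules Classification rule set; defaults to [default_rules()].
#' @param terms Candidate search terms for the ranking step.
#' @param narrow_term Narrower variant of the primary term for the
#'   differential-word analysis.
#' @param sample_size Review sample size per cohort (capped at the number
#'   of hits in the cohort).
#' @param deadline_days Legislative implantation deadline in days.
#' @param seed Master seed; per-cohort sampling seeds are derived from it.
#' @return A list of class `epr_analysis`.
#' @export
run_analysis <- function(corpus,
                         rules = default_rules(),
                         terms = default_search_terms,
                         narrow_term = "microch",
                         sample_size = 1000,
                         deadline_days = 84,
                         seed = 1) {
  counts <- count_corpus(corpus)
  cohorts <- split_cohorts(corpus)
  ranking <- rank_terms(cohorts$valid, terms, reference = "microc")
  search_a <- ranking$term[1]
  cohort_seeds <- with_local_seed(seed, sample.int(.Machine$integer.max - 1, 2))

  analyse_cohort <- function(cohort, cohort_seed) {
    hits <- find_hits(cohort, search_a)
    n_hits <- length(hits$record_refs)
    n_sample <- min(sample_size, n_hits)
    if (n_sample == 0) {
      empty <- tabulate_classifications(character(0))
      return(list(
        hits = hits, sampled_ids = integer(0), n_hits = n_hits,
        n_sampled = 0L, classification = empty, labels = character(0),
        ppv = NA_real_, n_implant = 0L, n_litter = 0L,
        ages = tibble::tibble(species = character(0), age_days = integer(0)),
        concurrent = tibble::tibble(event = character(0), count = integer(0)),
        seed = cohort_seed
      ))
    }
    ids <- sample_hits(hits, n_sample, seed = cohort_seed)
    sampled <- cohort[match(ids, cohort$record_id), , drop = FALSE]
    labels <- classify_hits(sampled, rules)
    classification <- tabulate_classifications(labels)
    implants <- sampled[labels == "implantation_event", , drop = FALSE]
    litter <- if (nrow(implants) > 0) detect_litter(implants) else logical(0)
    indiv <- implants[!litter, , drop = FALSE]
    ages <- tibble::tibble(
      species = indiv$species,
      age_days = ifelse(
        is.na(indiv$date_of_birth), NA_integer_,
        age_days(indiv$date_of_birth, indiv$visit_date)
      )
    )
    conc <- unlist(extract_concurrent(indiv))
    concurrent <- tibble::tibble(
      event = concurrent_classes(),
      count = as.integer(table(factor(conc, levels = concurrent_classes())))
    )
    list(
      hits = hits, sampled_ids = ids, n_hits = n_hits,
      n_sampled = as.integer(n_sample), classification = classification,
      labels = labels, ppv = ppv(nrow(implants), n_sample),
      n_implant = nrow(implants), n_litter = sum(litter),
      ages = ages, concurrent = concurrent, seed = cohort_seed
    )
  }

  valid <- analyse_cohort(cohorts$valid, cohort_seeds[1])
  invalid <- analyse_cohort(cohorts$invalid, cohort_seeds[2])

  ppv_test <- if (valid$n_sampled > 0 && invalid$n_sampled > 0 &&
                  (valid$n_implant + invalid$n_implant) > 0) {
    chisq_2x2(valid$n_implant, valid$n_sampled - valid$n_implant,
              invalid$n_implant, invalid$n_sampled - invalid$n_implant)
  } else NULL
  litter_test <- if (valid$n_implant > 0 && invalid$n_implant > 0 &&
                     (valid$n_litter + invalid$n_litter) > 0) {
    chisq_2x2(valid$n_litter, valid$n_implant - valid$n_litter,
              invalid$n_litter, invalid$n_implant - invalid$n_litter)
  } else NULL
  comparison <- if (valid$n_sampled > 0 && invalid$n_sampled > 0) {
    compare_category_proportions(valid$classification, invalid$classification)
  } else NULL

  all_ages <- dplyr::bind_rows(valid$ages, invalid$ages)
  all_ages <- all_ages[!is.na(all_ages$age_days), , drop = FALSE]
  dog_ages <- all_ages$age_days[all_ages$species == "dog"]
  cat_ages <- all_ages$age_days[all_ages$species == "cat"]
  age_summaries <- list(
    overall = if (nrow(all_ages) > 0) summarize_ages(all_ages$age_days) else NULL,
    dog = if (length(dog_ages) > 0) summarize_ages(dog_ages) else NULL,
    cat = if (length(cat_ages) > 0) summarize_ages(cat_ages) else NULL
  )
  species_test <- if (length(dog_ages) >= 2 && length(cat_ages) >= 2) {
    log_t_test(dog_ages, cat_ages)
  } else NULL
  compliance <- if (length(dog_ages) > 0) {
    compliance_fraction(dog_ages, deadline_days)
  } else NA_real_
  extrapolation <- if (!is.na(valid$ppv)) {
    extrapolate_events(valid$n_hits, valid$ppv)
  } else NULL
  diff_words <- differential_words(cohorts$valid, search_a, narrow_term)

  structure(
    list(
      counts = counts,
      ranking = ranking,
      search_term = search_a,
      narrow_term = narrow_term,
      valid = valid,
      invalid = invalid,
      ppv_test = ppv_test,
      litter_test = litter_test,
      comparison = comparison,
      age_summaries = age_summaries,
      species_age_test = species_test,
      compliance_dogs = compliance,
      deadline_days = deadline_days,
      extrapolation = extrapolation,
      differential_words = diff_words,
      linkage = linkage_report(corpus),
      conventions = list(
        yates = TRUE, quantile_type = 7L, denominator = "full_sample",
        master_seed = seed,
        cohort_seeds = c(valid = valid$seed, invalid = invalid$seed)
      )
    ),
    class = "epr_analysis"
  )
}

#' @export
print.epr_analysis <- function(x, ...) {
  cat("Implantation-event analysis\n")
  cat(sprintf("  corpus: %d rows, %d patients (%d dogs, %d cats), %d unique chips\n",
              x$counts$n_rows, x$counts$n_unique_patients, x$counts$n_dogs,
              x$counts$n_cats, x$counts$n_unique_chips))
  cat(sprintf("  primary search term: '%s' (%d records in valid cohort)\n",
              x$search_term, x$ranking$n_records[1]))
  cat(sprintf("  PPV: valid %.3f (n=%d), invalid %.3f (n=%d)\n",
              x$valid$ppv, x$valid$n_sampled, x$invalid$ppv, x$invalid$n_sampled))
  if (!is.null(x$ppv_test)) {
    cat(sprintf("  PPV difference: X2 = %.3f, p = %.3g (Yates)\n",
                x$ppv_test$statistic, x$ppv_test$p_value))
  }
  if (!is.null(x$age_summaries$dog)) {
    cat(sprintf("  dog age at implantation: median %.1f d (IQR %.2f, n=%d)\n",
                x$age_summaries$dog$median_days, x$age_summaries$dog$iqr_days,
                x$age_summaries$dog$n))
  }
  if (!is.null(x$age_summaries$cat)) {
    cat(sprintf("  cat age at implantation: median %.1f d (IQR %.2f, n=%d)\n",
                x$age_summaries$cat$median_days, x$age_summaries$cat$iqr_days,
                x$age_summaries$cat$n))
  }
  if (!is.null(x$species_age_test)) {
    cat(sprintf("  dog vs cat log-age t-test: t = %.3f, p = %.3g\n",
                x$species_age_test$t_statistic, x$species_age_test$p_value))
  }
  cat(sprintf("  duplicated chips: %d groups\n", x$linkage$n_groups))
  invisible(x)
}

#' Export the analysis report to files
#'
#' Writes one CSV per table (term ranking, the two cohort classification
#' tables, the cohort comparison, concurrent interactions, differential
#' words, linkage groups) plus a single `report.json` holding every
#' statistic with its inputs and convention flags. Filenames are stable and
#' re-export is byte-identical; the directory is created if missing.
#'
#' @param report An `epr_analysis` from [run_analysis()].
#' @param out_dir Output directory.
#' @return Character vector of the files written, invisibly.
#' @export
export_tables <- function(report, out_dir) {
  stopifnot(inherits(report, "epr_analysis"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  path <- function(name) file.path(out_dir, name)
  classification_tbl <- function(cohort) {
    tbl <- cohort$classification
    tbl$total_sampled <- attr(tbl, "total")
    tbl
  }
  concurrent_tbl <- dplyr::full_join(
    dplyr::rename(report$valid$concurrent, valid = "count"),
    dplyr::rename(report$invalid$concurrent, invalid = "count"),
    by = "event"
  )
  files <- c(
    ranking = "ranking.csv",
    classification_valid = "classification_valid.csv",
    classification_invalid = "classification_invalid.csv",
    comparison = "comparison.csv",
    concurrent = "concurrent.csv",
    differential_words = "differential_words.csv",
    linkage = "linkage.csv"
  )
  readr::write_csv(report$ranking, path(files["ranking"]), progress = FALSE)
  readr::write_csv(classification_tbl(report$valid), path(files["classification_valid"]),
                   progress = FALSE)
  readr::write_csv(classification_tbl(report$invalid), path(files["classification_invalid"]),
                   progress = FALSE)
  comparison <- report$comparison %||%
    tibble::tibble(category = character(0))
  readr::write_csv(comparison, path(files["comparison"]), progress = FALSE)
  readr::write_csv(concurrent_tbl, path(files["concurrent"]), progress = FALSE)
  readr::write_csv(report$differential_words, path(files["differential_words"]),
                   progress = FALSE)
  readr::write_csv(report$linkage$groups, path(files["linkage"]), progress = FALSE)

  json <- list(
    counts = report$counts,
    search_term = report$search_term,
    ppv = list(valid = report$valid$ppv, invalid = report$invalid$ppv,
               n_sampled = c(valid = report$valid$n_sampled,
                             invalid = report$invalid$n_sampled)),
    ppv_test = strip_table(report$ppv_test),
    litter_test = strip_table(report$litter_test),
    litter_counts = list(valid = report$valid$n_litter,
                         invalid = report$invalid$n_litter),
    age_summaries = report$age_summaries,
    species_age_test = unclass(report$species_age_test),
    compliance_dogs = report$compliance_dogs,
    deadline_days = report$deadline_days,
    extrapolation = report$extrapolation,
    linkage_by_class = report$linkage$by_class,
    linkage_multiplicity = report$linkage$multiplicity,
    conventions = report$conventions
  )
  jsonlite::write_json(json, path("report.json"), auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(file.path(out_dir, c(unname(files), "report.json")))
}

strip_table <- function(test) {
  if (is.null(test)) return(NULL)
  out <- unclass(test)
  out$table <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
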