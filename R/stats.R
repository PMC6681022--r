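#' Positive predictive value of a search
#'
#' The fraction of returned records that truly represent the target event
#' (here: a microchip implanted on the visit date), estimated from a
#' classified random sample of hits.
#'
#' @param true_positives Number of sampled hits representing the event.
#' @param total_hits Number of sampled hits reviewed (> 0).
#' @return The proportion `true_positives / total_hits`.
#' @export
#' @examples
#' ppv(257, 1000)
ppv <- function(true_positives, total_hits) {
  if (total_hits <= 0) abort("`total_hits` must be positive.")
  if (true_positives < 0 || true_positives > total_hits) {
    abort("`true_positives` must lie in [0, total_hits].")
  }
  true_positives / total_hits
}

#' Chi-squared test on a 2x2 table
#'
#' One-degree-of-freedom Pearson test of equal proportions between two
#' cohorts, with the Yates continuity correction applied by default
#' (|O - E| reduced by 0.5, floored at zero, before squaring). Rows are
#' cohorts, columns are yes/no counts.
#'
#' @param a,b First cohort: yes and no counts.
#' @param c,d Second cohort: yes and no counts.
#' @param yates Apply the continuity correction? Default `TRUE`.
#' @return A list of class `chisq_2x2` with elements `statistic`, `df`
#'   (always 1), `p_value`, `yates`, and the input `table`.
#' @export
#' @examples
#' chisq_2x2(257, 743, 155, 845)
chisq_2x2 <- function(a, b, c, d, yates = TRUE) {
  counts <- c(a, b, c, d)
  if (any(counts < 0)) abort("Counts must be non-negative.")
  m <- matrix(counts, nrow = 2, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    abort("Degenerate table: a row or column total is zero.")
  }
  fit <- suppressWarnings(stats::chisq.test(m, correct = yates))
  structure(
    list(
      statistic = unname(fit$statistic),
      df = 1L,
      p_value = unname(fit$p.value),
      yates = yates,
      table = m
    ),
    class = "chisq_2x2"
  )
}

#' @export
print.chisq_2x2 <- function(x, ...) {
  cat(sprintf("2x2 chi-squared%s: X2 = %.4g, df = 1, p = %.4g\n",
              if (x$yates) " (Yates-corrected)" else "", x$statistic, x$p_value))
  invisible(x)
}

#' Compare per-category proportions between two cohorts
#'
#' For each hit category, tests whether its frequency differs between the
#' valid- and invalid-chip cohorts using a Yates-corrected 2x2 chi-squared
#' with the full sample size of each cohort as denominator. Percentages are
#' additionally reported against the false-positive totals (hits minus
#' implantation events), the convention used when the categories are read
#' as "reasons for a false positive". Categories absent from both cohorts
#' are flagged `too_infrequent` and carry no test.
#'
#' @param valid,invalid Classification tables from
#'   [tabulate_classifications()] (with their `total` attributes).
#' @return A tibble with one row per category: counts, percentages of the
#'   false-positive totals, chi-squared statistic and p-value (`NA` when
#'   skipped), and a `too_infrequent` flag.
#' @export
compare_category_proportions <- function(valid, invalid) {
  n_valid <- attr(valid, "total")
  n_invalid <- attr(invalid, "total")
  stopifnot(!is.null(n_valid), !is.null(n_invalid))
  fp_valid <- n_valid - valid$count[valid$category == "implantation_event"]
  fp_invalid <- n_invalid - invalid$count[invalid$category == "implantation_event"]
  purrr::map_dfr(hit_categories(), function(cat) {
    cv <- valid$count[valid$category == cat]
    ci <- invalid$count[invalid$category == cat]
    skip <- (cv + ci) == 0
    if (!skip) {
      test <- chisq_2x2(cv, n_valid - cv, ci, n_invalid - ci)
      stat <- test$statistic
      p <- test$p_value
    } else {
      stat <- NA_real_
      p <- NA_real_
    }
    tibble::tibble(
      category = cat,
      count_valid = cv,
      count_invalid = ci,
      pct_valid_of_fp = if (fp_valid > 0) 100 * cv / fp_valid else NA_real_,
      pct_invalid_of_fp = if (fp_invalid > 0) 100 * ci / fp_invalid else NA_real_,
      chisq = stat,
      p_value = p,
      too_infrequent = skip
    )
  })
}

#' Continuity-corrected sample size for two proportions
#'
#' The normal-approximation sample size per group for detecting a
#' difference between two proportions at two-sided significance
#' `1 - confidence` and the given power,
#' \deqn{n = \frac{\left(z_{\alpha/2}\sqrt{2\bar p(1-\bar p)} +
#'   z_\beta\sqrt{p_1(1-p_1)+p_2(1-p_2)}\right)^2}{(p_1-p_2)^2},}
#' with \eqn{\bar p = (p_1+p_2)/2}, plus the Fleiss continuity correction
#' \eqn{2/|p_1-p_2|}, rounded up. The correction aligns the normal
#' approximation with the continuity-corrected chi-squared test that will
#' analyse the data.
#'
#' @param p1,p2 The two proportions to distinguish (must differ).
#' @param power Target power, in (0, 1). Default 0.8.
#' @param confidence Two-sided confidence level, in (0, 1). Default 0.95.
#' @return Integer sample size per group.
#' @export
#' @examples
#' fleiss_sample_size(0.09, 0.19)  # 208
fleiss_sample_size <- function(p1, p2, power = 0.8, confidence = 0.95) {
  if (p1 == p2) abort("`p1` and `p2` must differ; the sample size is undefined.")
  if (any(c(p1, p2, power, confidence) <= 0) || any(c(p1, p2, power, confidence) >= 1)) {
    abort("All of p1, p2, power, confidence must lie strictly in (0, 1).")
  }
  za <- qnorm(1 - (1 - confidence) / 2)
  zb <- qnorm(power)
  pbar <- (p1 + p2) / 2
  n <- (za * sqrt(2 * pbar * (1 - pbar)) + zb * sqrt(p1 * (1 - p1) + p2 * (1 - p2)))^2 /
    (p1 - p2)^2
  as.integer(ceiling(n + 2 / abs(p1 - p2)))
}

#' Simulated power of the Yates test at a given group size
#'
#' Monte-Carlo estimate of the power of the Yates-corrected 2x2 chi-squared
#' test to distinguish `p1` from `p2` with `n` subjects per group: binomial
#' counts are drawn in each group and the rejection rate at level
#' `1 - confidence` is returned. Used to check sample-size calculations
#' empirically.
#'
#' @inheritParams fleiss_sample_size
#' @param n Subjects per group.
#' @param reps Number of simulated trials.
#' @param seed Integer seed.
#' @return Estimated power (proportion of rejections).
#' @export
simulate_power <- function(p1, p2, n, reps = 20000, confidence = 0.95, seed = 1) {
  with_local_seed(seed, {
    x1 <- rbinom(reps, n, p1)
    x2 <- rbinom(reps, n, p2)
    # vectorised Yates-corrected statistic for tables (x1, n-x1 / x2, n-x2)
    total <- 2 * n
    colyes <- x1 + x2
    e11 <- n * colyes / total
    dev <- pmax(abs(x1 - e11) - 0.5, 0)
    stat <- dev^2 * 2 * (1 / e11 + 1 / (n - e11))  # |O-E| equal in all four cells
    crit <- stats::qchisq(confidence, df = 1)
    reject <- rep(FALSE, reps)
    ok <- colyes > 0 & colyes < total  # degenerate margins never reject
    reject[ok] <- stat[ok] > crit
    mean(reject)
  })
}

#' Age in whole days between two dates
#'
#' @param date_of_birth,event_date `Date` vectors.
#' @return Integer vector of non-negative day differences. An event
#'   preceding birth is an impossible record and raises an error rather
#'   than being dropped silently.
#' @export
age_days <- function(date_of_birth, event_date) {
  diff <- as.integer(as.Date(event_date) - as.Date(date_of_birth))
  if (any(diff < 0, na.rm = TRUE)) {
    abort("event_date precedes date_of_birth for at least one record.")
  }
  diff
}

#' Median and IQR of ages
#'
#' Quantiles use linear interpolation between order statistics
#' (`type = 7`, the default convention of mainstream statistics software);
#' the convention travels with the result.
#'
#' @param ages Non-empty numeric vector of ages in days.
#' @return A tibble with columns `n`, `median_days`, `iqr_days` and a
#'   `quantile_type` attribute.
#' @export
summarize_ages <- function(ages) {
  ages <- ages[!is.na(ages)]
  if (length(ages) == 0) abort("`ages` must contain at least one value.")
  q <- quantile(ages, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  out <- tibble::tibble(n = length(ages), median_days = q[2], iqr_days = q[3] - q[1])
  attr(out, "quantile_type") <- 7L
  out
}

#' Two-sample t-test on log-transformed ages
#'
#' Ages at implantation are right-skewed; the test is run on natural-log
#' ages to attain approximate normality. Zero ages are shifted by +1 day
#' before the log (recorded in the result). Welch's unequal-variance test
#' is the default; a pooled-variance option is available. The statistic is
#' invariant to the log base and to rescaling both groups by a common
#' positive factor.
#'
#' @param group_a,group_b Numeric age vectors (days), each of length >= 2.
#' @param var_equal Use the pooled-variance test? Default `FALSE` (Welch).
#' @return A list of class `log_t_test` with `t_statistic`, `p_value`,
#'   `df`, `var_equal` and `zero_shift` (number of ages shifted).
#' @export
log_t_test <- function(group_a, group_b, var_equal = FALSE) {
  group_a <- group_a[!is.na(group_a)]
  group_b <- group_b[!is.na(group_b)]
  if (length(group_a) < 2 || length(group_b) < 2) {
    abort("Each group needs at least two ages.")
  }
  if (any(group_a < 0) || any(group_b < 0)) abort("Ages must be non-negative.")
  shift <- sum(group_a == 0) + sum(group_b == 0)
  group_a[group_a == 0] <- 1
  group_b[group_b == 0] <- 1
  fit <- t.test(log(group_a), log(group_b), var.equal = var_equal)
  structure(
    list(
      t_statistic = unname(fit$statistic),
      p_value = unname(fit$p.value),
      df = unname(fit$parameter),
      var_equal = var_equal,
      zero_shift = shift
    ),
    class = "log_t_test"
  )
}

#' @export
print.log_t_test <- function(x, ...) {
  cat(sprintf("log-age t-test (%s): t = %.4f, df = %.1f, p = %.4g\n",
              if (x$var_equal) "pooled" else "Welch", x$t_statistic, x$df, x$p_value))
  invisible(x)
}

#' Extrapolate event counts from a PPV
#'
#' Scales a search's total hit count by its estimated PPV to project the
#' number of true events in the full corpus; the headline figure is the
#' product rounded to two significant digits, with the exact product kept
#' alongside.
#'
#' @param total_hits Total records returned by the search.
#' @param ppv Estimated positive predictive value.
#' @return A list with `exact` and `approximate` (2 significant figures).
#' @export
#' @examples
#' extrapolate_events(43365, 0.257)
extrapolate_events <- function(total_hits, ppv) {
  if (total_hits < 0 || ppv < 0 || ppv > 1) abort("Invalid inputs.")
  exact <- total_hits * ppv
  list(exact = exact, approximate = signif(exact, 2))
}

#' Fraction of events within a legislative deadline
#'
#' @param ages Non-empty numeric vector of ages at implantation (days).
#' @param deadline_days Deadline in days (e.g. 84 for a 12-week rule).
#' @return The fraction of ages less than or equal to the deadline.
#' @export
compliance_fraction <- function(ages, deadline_days) {
  ages <- ages[!is.na(ages)]
  if (length(ages) == 0) abort("`ages` must contain at least one value.")
  mean(ages <= deadline_days)
}
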