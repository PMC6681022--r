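test_that("ppv is an exact proportion with guarded inputs", {
  expect_equal(ppv(257, 1000), 0.257)
  expect_equal(ppv(0, 50), 0)
  expect_equal(ppv(50, 50), 1)
  expect_error(ppv(1, 0), "positive")
  expect_error(ppv(-1, 10))
  expect_error(ppv(11, 10))
})

test_that("the 2x2 test agrees with a longhand textbook oracle", {
  yates_oracle <- function(a, b, c, d, correct = TRUE) {
    o <- matrix(c(a, b, c, d), 2, byrow = TRUE)
    n <- sum(o)
    e <- outer(rowSums(o), colSums(o)) / n
    adj <- if (correct) pmin(0.5, abs(o - e)) else 0
    sum((abs(o - e) - adj)^2 / e)
  }
  set.seed(42)
  checked <- 0
  while (checked < 200) {
    cell <- sample(0:60, 4, replace = TRUE)
    m <- matrix(cell, 2, byrow = TRUE)
    if (any(rowSums(m) == 0) || any(colSums(m) == 0)) next
    for (correct in c(TRUE, FALSE)) {
      res <- chisq_2x2(cell[1], cell[2], cell[3], cell[4], yates = correct)
      expect_equal(res$statistic,
                   yates_oracle(cell[1], cell[2], cell[3], cell[4], correct),
                   tolerance = 1e-9)
      expect_equal(res$p_value, stats::pchisq(res$statistic, 1, lower.tail = FALSE),
                   tolerance = 1e-9)
    }
    # correction can only shrink the statistic; swaps leave it unchanged
    expect_lte(chisq_2x2(cell[1], cell[2], cell[3], cell[4])$statistic,
               chisq_2x2(cell[1], cell[2], cell[3], cell[4], yates = FALSE)$statistic)
    expect_equal(chisq_2x2(cell[1], cell[2], cell[3], cell[4])$statistic,
                 chisq_2x2(cell[3], cell[4], cell[1], cell[2])$statistic)
    expect_equal(chisq_2x2(cell[1], cell[2], cell[3], cell[4])$statistic,
                 chisq_2x2(cell[2], cell[1], cell[4], cell[3])$statistic)
    checked <- checked + 1
  }
})

test_that("degenerate and null tables are handled", {
  expect_equal(chisq_2x2(10, 10, 10, 10)$statistic, 0)
  expect_error(chisq_2x2(0, 0, 5, 5), "Degenerate")
  expect_error(chisq_2x2(-1, 2, 3, 4), "non-negative")
})

test_that("category comparison uses full-sample denominators and flags rare rows", {
  valid <- tabulate_classifications(c(
    rep("implantation_event", 257), rep("blank_prepopulated_form", 458),
    rep("none_of_the_above", 285)
  ))
  invalid <- tabulate_classifications(c(
    rep("implantation_event", 155), rep("blank_prepopulated_form", 385),
    rep("none_of_the_above", 460)
  ))
  cmp <- compare_category_proportions(valid, invalid)
  blank <- cmp[cmp$category == "blank_prepopulated_form", ]
  expect_equal(round(blank$chisq, 2), 10.63)
  expect_equal(blank$pct_valid_of_fp, 100 * 458 / 743)
  expect_equal(blank$pct_invalid_of_fp, 100 * 385 / 845)
  rare <- cmp[cmp$category == "owner_refusal", ]
  expect_true(rare$too_infrequent)
  expect_true(is.na(rare$chisq))
})

test_that("continuity-corrected sample size matches the closed form", {
  expect_equal(fleiss_sample_size(0.09, 0.19, 0.80, 0.95), 208L)
  expect_equal(fleiss_sample_size(0.19, 0.09, 0.80, 0.95), 208L)
  # hand recomputation of the uncorrected term plus 2/|p1-p2|
  za <- qnorm(0.975); zb <- qnorm(0.8); pbar <- 0.14
  n <- (za * sqrt(2 * pbar * 0.86) + zb * sqrt(0.09 * 0.91 + 0.19 * 0.81))^2 / 0.01
  expect_equal(fleiss_sample_size(0.09, 0.19), as.integer(ceiling(n + 20)))
  expect_error(fleiss_sample_size(0.2, 0.2), "differ")
  expect_error(fleiss_sample_size(0, 0.5), "strictly")
})

test_that("simulated power behaves at the extremes", {
  # enormous effect: essentially always detected
  expect_gt(simulate_power(0.05, 0.95, n = 50, reps = 2000, seed = 2), 0.99)
  # no effect: rejection rate is the test size, not more than ~alpha
  expect_lt(simulate_power(0.5, 0.5, n = 100, reps = 4000, seed = 3), 0.07)
})

test_that("age arithmetic and summaries follow stated conventions", {
  expect_equal(age_days(as.Date("2017-01-01"), as.Date("2017-03-16")), 74L)
  expect_equal(age_days(as.Date("2017-01-01"), as.Date("2017-01-01")), 0L)
  expect_error(age_days(as.Date("2017-03-16"), as.Date("2017-01-01")), "precedes")

  s <- summarize_ages(c(1, 2, 3, 4, 5))
  expect_equal(s$median_days, 3)
  expect_equal(s$iqr_days, 2)
  expect_equal(summarize_ages(7)$iqr_days, 0)
  expect_equal(summarize_ages(7)$median_days, 7)
  expect_error(summarize_ages(numeric(0)), "at least one")
})

test_that("the log t-test matches hand computation and its symmetries", {
  a <- c(2, 4, 8, 16); b <- c(4, 8, 16, 32)
  res <- log_t_test(a, b)
  # in log2 units the groups are 1:4 and 2:5; equal variances 5/3
  t_hand <- (mean(1:4) - mean(2:5)) / sqrt(2 * (5 / 3) / 4)
  expect_equal(res$t_statistic, t_hand, tolerance = 1e-12)
  expect_equal(log_t_test(b, a)$t_statistic, -res$t_statistic)
  expect_equal(log_t_test(a, a)$t_statistic, 0)
  # invariance to a common positive rescaling
  expect_equal(log_t_test(7 * a, 7 * b)$t_statistic, res$t_statistic,
               tolerance = 1e-12)
  zero <- log_t_test(c(0, 3, 9), c(1, 4, 16))
  expect_equal(zero$zero_shift, 1)
  expect_error(log_t_test(1, c(2, 3)), "at least two")
})

test_that("extrapolation and compliance are simple monotone summaries", {
  ex <- extrapolate_events(43365, 0.257)
  expect_equal(ex$exact, 11144.805)
  expect_equal(ex$approximate, 11000)
  expect_equal(extrapolate_events(500, 0)$exact, 0)
  expect_equal(extrapolate_events(500, 1)$exact, 500)

  expect_equal(compliance_fraction(c(10, 80, 100), 84), 2 / 3)
  expect_equal(compliance_fraction(c(100, 120), 84), 0)
  expect_error(compliance_fraction(numeric(0), 84), "at least one")
})
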