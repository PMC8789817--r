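#' Variance-corrected paired t-test over resampled splits
#'
#' Paired t-test over scores collected on overlapping resamples (subject
#' split-halves, repeated cross-validation folds), with the variance inflated
#' by `(1/J + correction_ratio)` to account for the non-independence of the
#' resamples; `correction_ratio` is the test/train size ratio n2/n1 (1 for
#' equal split-halves, 0 recovers the classical paired t-test).  Correlation
#' scores are differenced on the Fisher-z scale (pinned, consistent with the
#' Fisher-z averaging convention); set `fisher = FALSE` for scores that are
#' not correlations.
#'
#' @param scores_a,scores_b equal-length paired score vectors over J >= 2
#'   splits.
#' @param correction_ratio nonnegative correction ratio n2/n1.
#' @param fisher difference on the atanh scale (default TRUE).
#' @return An object of class `corrected_test_result`: `t_statistic`,
#'   `p_value` (two-sided, J-1 d.o.f.), `J`, `correction_ratio`,
#'   `mean_difference` (on the testing scale).
#' @export
corrected_paired_ttest <- function(scores_a, scores_b, correction_ratio = 1,
                                   fisher = TRUE) {
  J <- length(scores_a)
  if (length(scores_b) != J) input_error("score lists must have equal length")
  if (J < 2L) ipcl_error("need J >= 2 paired scores", "ipclversa_degenerate_test_error")
  if (correction_ratio < 0) config_error("correction_ratio must be >= 0")
  clip <- function(r) pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7)
  d <- if (fisher) atanh(clip(scores_a)) - atanh(clip(scores_b)) else scores_a - scores_b
  v <- stats::var(d)
  md <- mean(d)
  if (v < 1e-300) {
    # identical paired scores: no evidence of a difference (t = 0, p = 1);
    # zero variance with a nonzero mean is off the t-distribution entirely
    t_stat <- if (abs(md) < 1e-300) 0 else sign(md) * Inf
  } else {
    t_stat <- md / sqrt(v * (1 / J + correction_ratio))
  }
  p <- 2 * stats::pt(abs(t_stat), df = J - 1, lower.tail = FALSE)
  structure(list(t_statistic = t_stat, p_value = p, J = J,
                 correction_ratio = correction_ratio, mean_difference = md),
            class = "corrected_test_result")
}

#' @export
print.corrected_test_result <- function(x, ...) {
  cat(sprintf("corrected paired t = %.4f, p = %.4g (J = %d, ratio = %.3g)\n",
              x$t_statistic, x$p_value, x$J, x$correction_ratio))
  invisible(x)
}

#' Adjusted confidence interval for split-half correlations
#'
#' On the Fisher-z scale: `mean +/- t_{J-1} * sqrt(var * (1/J +
#' correction_ratio))`, mapped back through `tanh`.  The inflation term
#' widens the interval relative to the classical `1/J` standard error,
#' accounting for the shared subjects across splits.
#'
#' @param rs correlations over J >= 2 splits.
#' @param correction_ratio nonnegative correction ratio n2/n1.
#' @param level confidence level (default 0.95).
#' @return Length-2 vector `c(low, high)` on the correlation scale.
#' @export
adjusted_ci <- function(rs, correction_ratio = 1, level = 0.95) {
  J <- length(rs)
  if (J < 2L) ipcl_error("need J >= 2 correlations", "ipclversa_degenerate_test_error")
  z <- atanh(pmin(pmax(rs, -(1 - 1e-7)), 1 - 1e-7))
  m <- mean(z)
  se <- sqrt(stats::var(z) * (1 / J + correction_ratio))
  tq <- stats::qt((1 + level) / 2, df = J - 1)
  tanh(c(m - tq * se, m + tq * se))
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha family-wise alpha.
#' @param m number of family-wise tests (>= 1).
#' @return `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m = 1L) {
  if (!is_count(m)) input_error("m must be a count >= 1")
  if (alpha <= 0 || alpha > 1) input_error("alpha must be in (0, 1]")
  alpha / m
}
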