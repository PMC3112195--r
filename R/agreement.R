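# Agreement and variability statistics: Bland-Altman bias with limits of
# agreement, duplicate-based intraindividual CV and its analytical/biological
# decomposition, distribution summaries, paired significance tests, and the
# prevalence misclassification report.

#' Bland-Altman agreement on percent differences
#'
#' Per pair the percent difference is
#' `d = 100 * (corrected - fasting) / denominator`, where the denominator is
#' the true-fasting value (default — the bias is then read as "percent above
#' the fasting measurement") or the classical pair mean. Bias is `mean(d)`,
#' the 95% limits of agreement are `bias +/- 1.96 * sd(d)`, the CI of the
#' bias uses the standard error `sd(d)/sqrt(n)` and the CI of each limit of
#' agreement the approximation `sqrt(3/n) * sd(d)`.
#'
#' @param corrected,fasting paired positive measurements, mmol/L.
#' @param denominator_mode `"true_fasting"` or `"pair_mean"`.
#' @return an object of class `agreement_result`: `bias`, `sd_d`, `loa_low`,
#'   `loa_high`, 95% intervals `ci_bias`, `ci_loa_low`, `ci_loa_high` (all
#'   percent), `n`, `denominator_mode`, and the per-pair differences `d`
#'   with the fasting values `reference` (for plotting).
#' @examples
#' x <- c(1.1, 0.9, 1.1, 0.9)
#' bland_altman(x, rep(1, 4))
#' @export
bland_altman <- function(corrected, fasting,
                         denominator_mode = c("true_fasting", "pair_mean")) {
  denominator_mode <- match.arg(denominator_mode)
  n <- length(corrected)
  if (n != length(fasting)) stop("`corrected` and `fasting` lengths differ")
  if (n < 2) stop("at least 2 pairs are required")
  if (any(corrected <= 0 | fasting <= 0, na.rm = TRUE))
    stop("all measurements must be positive")
  denom <- switch(denominator_mode,
                  true_fasting = fasting,
                  pair_mean = (corrected + fasting) / 2)
  d <- 100 * (corrected - fasting) / denom
  bias <- mean(d)
  s <- sd(d)
  se_loa <- sqrt(3 / n) * s
  structure(list(
    bias = bias, sd_d = s,
    loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
    ci_bias = bias + c(-1, 1) * 1.96 * s / sqrt(n),
    ci_loa_low = bias - 1.96 * s + c(-1, 1) * 1.96 * se_loa,
    ci_loa_high = bias + 1.96 * s + c(-1, 1) * 1.96 * se_loa,
    n = n, denominator_mode = denominator_mode,
    d = d, reference = fasting), class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf(
    "Bland-Altman agreement (n = %d, denominator: %s)\n", x$n,
    x$denominator_mode))
  cat(sprintf("  bias  %+.2f%%  (95%% CI %.2f to %.2f)\n",
              x$bias, x$ci_bias[1], x$ci_bias[2]))
  cat(sprintf("  LoA   %.2f%% to %.2f%%\n", x$loa_low, x$loa_high))
  invisible(x)
}

#' Plot a Bland-Altman agreement result
#'
#' Percent difference against the reference measurement, with the bias
#' (solid), 95% limits of agreement (dashed) and their confidence intervals
#' (dotted).
#'
#' @param x an [bland_altman()] result.
#' @param xlab,ylab,... passed to [plot()].
#' @export
plot.agreement_result <- function(x, xlab = "Reference Tg (mmol/L)",
                                  ylab = "Difference (%)", ...) {
  plot(x$reference, x$d, pch = 20, col = "grey40",
       xlab = xlab, ylab = ylab, ...)
  abline(h = 0, lwd = 1)
  abline(h = x$bias, lwd = 2)
  abline(h = c(x$loa_low, x$loa_high), lty = 2)
  abline(h = c(x$ci_bias, x$ci_loa_low, x$ci_loa_high), lty = 3)
  invisible(x)
}

#' Duplicate-based intraindividual coefficient of variation
#'
#' From paired measurements of the same subject months apart: the
#' per-subject SD from a duplicate pair is `|x1 - x2| / sqrt(2)` and the
#' per-subject CV is `100 * SD / mean(pair)`. The total intraindividual CV
#' (`cv_tb`) is summarised as the mean and 25th/75th percentiles of the
#' per-subject CVs, and the biological component follows from the
#' decomposition `cv_tb^2 = cv_anal^2 + cv_biol^2`, truncated at zero when
#' the analytical CV exceeds the total.
#'
#' @param x1,x2 paired positive measurements.
#' @param cv_anal analytical CV of the assay, percent.
#' @return list of class `cv_summary`: `cv_tb_mean`, `cv_tb_q25`,
#'   `cv_tb_q75`, `cv_anal`, `cv_biol` (all percent), `n` (pairs used).
#' @examples
#' duplicate_cv(c(1.0, 1.1), c(1.2, 0.9), cv_anal = 1.5)
#' @export
duplicate_cv <- function(x1, x2, cv_anal = 0) {
  if (length(x1) != length(x2)) stop("`x1` and `x2` lengths differ")
  if (length(x1) < 1) stop("at least one pair is required")
  if (cv_anal < 0) stop("`cv_anal` must be non-negative")
  m <- (x1 + x2) / 2
  zero <- !is.na(m) & m == 0
  if (any(zero)) {
    warning(sum(zero), " pair(s) with zero mean excluded")
  }
  keep <- !is.na(m) & m > 0
  if (!any(keep)) stop("no usable pairs after exclusions")
  cv_i <- 100 * (abs(x1[keep] - x2[keep]) / sqrt(2)) / m[keep]
  cv_tb <- mean(cv_i)
  q <- quantile(cv_i, c(0.25, 0.75), names = FALSE)
  structure(list(cv_tb_mean = cv_tb, cv_tb_q25 = q[1], cv_tb_q75 = q[2],
                 cv_anal = cv_anal,
                 cv_biol = sqrt(max(0, cv_tb^2 - cv_anal^2)),
                 n = sum(keep)), class = "cv_summary")
}

#' Distribution summary: mean, median and quartiles
#'
#' Median and quartiles use linear interpolation between the closest order
#' statistics (the default convention of [stats::quantile()], type 7).
#'
#' @param values numeric vector, at least one value; `NA`s removed.
#' @return named numeric vector `mean`, `median`, `q25`, `q75`.
#' @export
quantile_summary <- function(values) {
  values <- values[!is.na(values)]
  if (!length(values)) stop("`values` must contain at least one value")
  q <- quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  c(mean = mean(values), median = q[2], q25 = q[1], q75 = q[3])
}

#' Wilcoxon matched-pairs signed-rank test
#'
#' Two-sided p-value from the normal approximation with tie correction and
#' continuity correction; zero differences are dropped first. When every
#' difference is zero the test is degenerate and p = 1 is returned with a
#' warning.
#'
#' @param x,y paired measurements, or differences in `x` with `y = NULL`.
#' @return list with `statistic` (sum of positive ranks, V) and `p_value`.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL) {
  d <- if (is.null(y)) x else x - y
  d <- d[!is.na(d)]
  d <- d[d != 0]
  if (!length(d)) {
    warning("all paired differences are zero; p = 1")
    return(list(statistic = 0, p_value = 1))
  }
  ht <- suppressWarnings(wilcox.test(d, exact = FALSE, correct = TRUE))
  list(statistic = unname(ht$statistic), p_value = ht$p.value)
}

#' Chi-square comparison of two prevalences
#'
#' Pearson chi-square on the 2x2 table of positives/negatives in two groups,
#' one degree of freedom, no continuity correction. For paired designs (the
#' same subjects classified twice) [mcnemar_prevalence()] is the matched
#' alternative; the unpaired chi-square is provided as the conventional
#' survey-report comparison.
#'
#' @param n1_pos,n1_tot,n2_pos,n2_tot positive counts and totals.
#' @return list with `statistic` and `p_value`.
#' @examples
#' chi2_prevalence(30, 100, 10, 100)  # statistic 12.5
#' @export
chi2_prevalence <- function(n1_pos, n1_tot, n2_pos, n2_tot) {
  if (n1_tot <= 0 || n2_tot <= 0) stop("group totals must be positive")
  if (n1_pos < 0 || n2_pos < 0 || n1_pos > n1_tot || n2_pos > n2_tot)
    stop("positive counts must lie in [0, total]")
  tab <- rbind(c(n1_pos, n1_tot - n1_pos), c(n2_pos, n2_tot - n2_pos))
  if (any(colSums(tab) == 0))
    stop("a margin of the 2x2 table is zero; the statistic is undefined")
  ht <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(statistic = unname(ht$statistic), p_value = ht$p.value)
}

#' McNemar test for paired binary classifications
#'
#' Matched-pairs alternative to [chi2_prevalence()] when the two
#' classifications are of the same subjects (with continuity correction).
#'
#' @param status1,status2 logical vectors of the paired classifications;
#'   pairs with any `NA` are dropped.
#' @return list with `statistic`, `p_value` and the discordant counts `b`
#'   (`status1` only) and `c` (`status2` only).
#' @export
mcnemar_prevalence <- function(status1, status2) {
  keep <- !is.na(status1) & !is.na(status2)
  s1 <- status1[keep]; s2 <- status2[keep]
  b <- sum(s1 & !s2); cc <- sum(!s1 & s2)
  if (b + cc == 0) {
    warning("no discordant pairs; p = 1")
    return(list(statistic = 0, p_value = 1, b = b, c = cc))
  }
  tab <- rbind(c(sum(s1 & s2), b), c(cc, sum(!s1 & !s2)))
  ht <- mcnemar.test(tab)
  list(statistic = unname(ht$statistic), p_value = ht$p.value, b = b, c = cc)
}

#' Prevalence misclassification in percentage points
#'
#' The misclassification induced by a surrogate measurement is the absolute
#' difference between the prevalence computed from it and the prevalence
#' computed from the reference measurement; the signed difference
#' (comparator minus reference) is reported alongside.
#'
#' @param prev_reference,prev_comparator prevalences in percent, \[0, 100].
#' @return list with `diff_pp` (absolute, percentage points) and
#'   `signed_pp` (comparator - reference).
#' @examples
#' misclassification_report(56.4, 51.3)  # 5.1 pp
#' @export
misclassification_report <- function(prev_reference, prev_comparator) {
  if (any(c(prev_reference, prev_comparator) < 0) ||
      any(c(prev_reference, prev_comparator) > 100))
    stop("prevalences must lie in [0, 100]")
  list(diff_pp = abs(prev_comparator - prev_reference),
       signed_pp = prev_comparator - prev_reference)
}
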