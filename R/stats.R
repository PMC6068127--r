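#' Root-mean-square coefficient of variation (short-term precision)
#'
#' The standard densitometric precision-error metric over repeat
#' measurements: `CV%RMS = 100 * sqrt(mean_i((SD_i / |mean_i|)^2))` across
#' subjects `i`, with the n-1 SD denominator. Signed metrics (compressive
#' stress/strain) use the absolute subject mean.
#'
#' @param values List with one numeric vector of repeat measurements per
#'   subject (each >= 2 repeats).
#' @return CV%RMS in percent.
#' @export
cv_rms <- function(values) {
  if (!is.list(values)) values <- list(values)
  if (any(lengths(values) < 2)) stop("each subject needs >= 2 repeats")
  means <- vapply(values, mean, 0)
  if (any(means == 0))
    stop("subject mean of exactly 0 (subject ",
         paste(which(means == 0), collapse = ", "),
         "): CV undefined")
  sds <- vapply(values, stats::sd, 0)
  100 * sqrt(mean((sds / abs(means))^2))
}

# adjusted Fisher-Pearson skewness / excess kurtosis and their small-sample
# standard errors (the conventions used by common statistical software)
skew_kurt_z <- function(x) {
  n <- length(x)
  if (n < 4) stop("need n >= 4 for the normality gate")
  m <- mean(x)
  s <- stats::sd(x)
  if (s == 0) return(c(z_skew = Inf, z_kurt = Inf))
  m2 <- mean((x - m)^2); m3 <- mean((x - m)^3); m4 <- mean((x - m)^4)
  g1 <- m3 / m2^1.5
  g2 <- m4 / m2^2 - 3
  G1 <- g1 * sqrt(n * (n - 1)) / (n - 2)
  G2 <- ((n + 1) * g2 + 6) * (n - 1) / ((n - 2) * (n - 3))
  se_skew <- sqrt(6 * n * (n - 1) / ((n - 2) * (n + 1) * (n + 3)))
  se_kurt <- 2 * se_skew * sqrt((n^2 - 1) / ((n - 3) * (n + 5)))
  c(z_skew = G1 / se_skew, z_kurt = G2 / se_kurt)
}

#' Normality gate by skewness/kurtosis Z-scores
#'
#' A sample is flagged non-normal when its skewness or excess-kurtosis
#' Z-score (statistic over its small-sample standard error) falls outside
#' +/- 1.96. Constant samples are non-normal by convention. The decision is
#' invariant under affine transforms (standardised moments).
#'
#' @param sample Numeric vector, n >= 4.
#' @param limit Z-score limit (default 1.96).
#' @return `"normal"` or `"non_normal"`.
#' @export
normality_gate <- function(sample, limit = 1.96) {
  z <- skew_kurt_z(sample)
  if (any(!is.finite(z)) || any(abs(z) > limit)) "non_normal" else "normal"
}

#' Hodges-Lehmann two-sample location-shift estimator
#'
#' Median of all pairwise differences `x_i - y_j`.
#'
#' @param x,y Numeric samples.
#' @return The HL estimate of the location shift of `x` relative to `y`.
#' @export
hl_estimator <- function(x, y) {
  stats::median(as.numeric(outer(x, y, `-`)))
}

#' Compare two groups with the normality-gated test procedure
#'
#' If both samples pass the [normality_gate()], a classic pooled-variance
#' unpaired t-test with mean difference and t-based 95% CI; otherwise an
#' exact Mann-Whitney U test with the Hodges-Lehmann shift estimate and its
#' distribution-based 95% CI. Cohen's d uses an externally supplied SD when
#' given (e.g. the all-scans SD) and the pooled SD otherwise. The percent
#' difference is relative to the reference (normal) group's central value.
#'
#' @param oa_values,normal_values Numeric group samples (n >= 2 each).
#' @param sd_for_d Optional SD for the Cohen's d denominator.
#' @param conf_level Confidence level (default 0.95).
#' @return A one-row data frame (`comparison_row`): central values and SDs
#'   per group, absolute and percent difference, CI bounds, p-value, Cohen's
#'   d, `test_used` and `distribution` flags.
#' @export
compare_groups <- function(oa_values, normal_values, sd_for_d = NULL,
                           conf_level = 0.95) {
  if (length(oa_values) < 2 || length(normal_values) < 2)
    stop("both groups need n >= 2")
  all_tied <- stats::sd(c(oa_values, normal_values)) == 0
  gate <- if (all_tied) "non_normal" else {
    if (normality_gate(oa_values) == "normal" &&
        normality_gate(normal_values) == "normal") "normal" else "non_normal"
  }
  n1 <- length(oa_values); n2 <- length(normal_values)
  pooled_sd <- sqrt(((n1 - 1) * stats::var(oa_values) +
                       (n2 - 1) * stats::var(normal_values)) / (n1 + n2 - 2))
  if (all_tied) {
    ctr_oa <- mean(oa_values); ctr_no <- mean(normal_values)
    diff_abs <- ctr_oa - ctr_no
    p <- 1; ci <- c(diff_abs, diff_abs); test <- "mann_whitney"
  } else if (gate == "normal") {
    tt <- stats::t.test(oa_values, normal_values, var.equal = TRUE,
                        conf.level = conf_level)
    ctr_oa <- mean(oa_values); ctr_no <- mean(normal_values)
    diff_abs <- ctr_oa - ctr_no
    p <- tt$p.value; ci <- as.numeric(tt$conf.int); test <- "t"
  } else {
    wt <- suppressWarnings(
      stats::wilcox.test(oa_values, normal_values, conf.int = TRUE,
                         conf.level = conf_level,
                         exact = n1 <= 12 && n2 <= 12))
    ctr_oa <- stats::median(oa_values); ctr_no <- stats::median(normal_values)
    diff_abs <- hl_estimator(oa_values, normal_values)
    p <- wt$p.value; ci <- as.numeric(wt$conf.int); test <- "mann_whitney"
  }
  sd_d <- if (is.null(sd_for_d)) pooled_sd else sd_for_d
  d <- if (sd_d > 0) abs(diff_abs) / sd_d else NA_real_
  data.frame(oa_center = ctr_oa, oa_sd = stats::sd(oa_values),
             normal_center = ctr_no, normal_sd = stats::sd(normal_values),
             difference_absolute = diff_abs,
             difference_percent = if (ctr_no != 0)
               100 * diff_abs / abs(ctr_no) else NA_real_,
             ci_low = min(ci), ci_high = max(ci), p_value = p,
             cohens_d = d, d_large = !is.na(d) && d > 0.8,
             test_used = test, distribution = gate,
             stringsAsFactors = FALSE)
}

#' Cohen's d effect size
#'
#' `d = |difference| / sd`; d > 0.8 is conventionally a large effect.
#'
#' @param diff Group difference (any sign).
#' @param sd Standard deviation used as the denominator (> 0): the pooled SD
#'   or the all-scans SD depending on convention.
#' @return Named list with `d` and logical `large`.
#' @export
effect_size <- function(diff, sd) {
  if (!is.finite(sd) || sd <= 0) stop("sd must be > 0")
  d <- abs(diff) / sd
  list(d = d, large = d > 0.8)
}
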