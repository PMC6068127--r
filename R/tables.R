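#' Published reference values for regional proximal-tibia FE metrics
#'
#' Regional minimum principal stress and strain and compartmental stiffness
#' values (all-scans mean/SD, CV%RMS precision, OA and normal group central
#' values and SDs) as printed by a published in-vivo QCT-FE precision study
#' of OA and normal knees. Used for worked-example checks of the table
#' aggregation utilities and as reference magnitudes.
#'
#' @return Data frame with columns `table` (`min_principal_stress`,
#'   `min_principal_strain`, `stiffness`), `region`, `all_mean`, `all_sd`,
#'   `cv_rms`, `oa_center`, `oa_sd`, `normal_center`, `normal_sd`.
#' @export
reference_regional_values <- function() {
  path <- system.file("extdata", "reference_regional_values.csv",
                      package = "tibiamech", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Summarise a precision column
#'
#' @param tbl Data frame with `region` and `cv_rms` columns (one metric).
#' @return List with `mean_cv`, `max_cv`, `min_cv` and `n_regions`.
#' @export
summarize_precision <- function(tbl) {
  stopifnot(all(c("region", "cv_rms") %in% names(tbl)))
  list(mean_cv = mean(tbl$cv_rms), max_cv = max(tbl$cv_rms),
       min_cv = min(tbl$cv_rms), n_regions = nrow(tbl))
}

#' Percent difference relative to a reference value
#'
#' @param value,reference Numeric; the difference `value - reference` is
#'   expressed in percent of `|reference|`.
#' @return Percent difference.
#' @export
percent_difference <- function(value, reference) {
  if (reference == 0) stop("reference value is zero")
  100 * (value - reference) / abs(reference)
}

comparison_columns <- c("region", "metric", "all_mean", "all_sd", "cv_rms",
                        "oa_center", "oa_sd", "normal_center", "normal_sd",
                        "difference_absolute", "difference_percent",
                        "ci_low", "ci_high", "p_value", "cohens_d",
                        "test_used", "distribution")

#' Write / read a comparison table as CSV
#'
#' Column order mirrors the report layout: all-scans mean and SD, CV%RMS,
#' OA and normal central values and SDs, absolute and percent difference,
#' 95% CI, p-value and Cohen's d. Reports carry no multiple-testing
#' correction across regions; interpret per-region p-values accordingly.
#'
#' @param tbl Comparison data frame (a subset of the standard columns is
#'   allowed; missing ones are filled with NA on write).
#' @param path Output CSV path.
#' @return `write_comparison_csv` returns `path` invisibly;
#'   `read_comparison_csv` returns the data frame.
#' @export
write_comparison_csv <- function(tbl, path) {
  for (cc in setdiff(comparison_columns, names(tbl))) tbl[[cc]] <- NA
  utils::write.csv(tbl[, comparison_columns], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_comparison_csv
#' @export
read_comparison_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Render a comparison table as Markdown
#'
#' Rounded for reporting: stress to 2 decimals, microstrain and stiffness to
#' integers, percents to 1 decimal.
#'
#' @param tbl Comparison data frame.
#' @param metric One of `"stress"`, `"strain"`, `"stiffness"` (controls
#'   rounding).
#' @return Character vector of Markdown lines.
#' @export
format_comparison_md <- function(tbl, metric = c("stress", "strain",
                                                 "stiffness")) {
  metric <- match.arg(metric)
  dig <- if (metric == "stress") 2 else 0
  num <- function(x) ifelse(is.na(x), "", formatC(x, format = "f",
                                                  digits = dig))
  pct <- function(x) ifelse(is.na(x), "", formatC(x, format = "f",
                                                  digits = 1))
  hdr <- c("Region", "Mean", "SD", "CV%RMS", "OA", "OA SD", "Normal",
           "Normal SD", "Diff", "Diff %", "CI low", "CI high", "p", "d")
  lines <- c(paste("|", paste(hdr, collapse = " | "), "|"),
             paste("|", paste(rep("---", length(hdr)), collapse = " | "),
                   "|"))
  for (i in seq_len(nrow(tbl))) {
    r <- tbl[i, ]
    lines <- c(lines, paste("|", paste(c(
      r$region, num(r$all_mean), num(r$all_sd), pct(r$cv_rms),
      num(r$oa_center), num(r$oa_sd), num(r$normal_center),
      num(r$normal_sd), num(r$difference_absolute),
      pct(r$difference_percent), num(r$ci_low), num(r$ci_high),
      ifelse(is.na(r$p_value), "", formatC(r$p_value, format = "f",
                                           digits = 3)),
      ifelse(is.na(r$cohens_d), "", formatC(r$cohens_d, format = "f",
                                            digits = 2))),
      collapse = " | "), "|"))
  }
  lines
}
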