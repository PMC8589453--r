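#' Derived aging metrics: delta age and age ratio
#'
#' Joins biological-age predictions back to the cohort and computes, per
#' subject, `dage = ba - ca` (years of age acceleration) and
#' `age_ratio = ba / ca` (a point-in-time rate-of-aging surrogate: 1 means
#' BA matches CA, values above 1 indicate faster-than-calendar aging).
#'
#' @param results Prediction data frame from [predict.bioage()] or
#'   [phenotypic_age()] (columns `subject_id`, `estimator`, `ba`).
#' @param cohort Cohort data frame with `subject_id`, `ca` (and optionally
#'   `group`).
#' @return Data frame `subject_id`, `estimator`, `ba`, `ca`, `dage`,
#'   `age_ratio` (plus `group` when available), one row per result row.
#' @export
aging_metrics <- function(results, cohort) {
  check_columns(results, c("subject_id", "estimator", "ba"), "aging_metrics")
  check_columns(cohort, c("subject_id", "ca"), "aging_metrics")
  idx <- match(results$subject_id, cohort$subject_id)
  if (anyNA(idx)) {
    stop_schema("aging_metrics: ", sum(is.na(idx)),
                " result row(s) have no matching cohort subject")
  }
  ca <- cohort$ca[idx]
  if (any(ca <= 0)) {
    stop_domain("aging_metrics: age ratio undefined for ca <= 0")
  }
  out <- data.frame(subject_id = results$subject_id,
                    estimator = results$estimator,
                    ba = results$ba,
                    ca = ca,
                    dage = results$ba - ca,
                    age_ratio = results$ba / ca,
                    stringsAsFactors = FALSE)
  if ("group" %in% names(cohort)) out$group <- cohort$group[idx]
  out
}

#' Compare delta age between two groups
#'
#' Reports the mean difference in delta age (group A minus group B) and a
#' two-sided Wilcoxon rank-sum p-value. Works for any stratification —
#' disease status, BMI bins, smoking strata — since the comparison takes
#' two pre-formed metric tables.
#'
#' @param metrics_a,metrics_b [aging_metrics()] tables (or any data frames
#'   with a `dage` column), each with at least 2 rows.
#' @param label_a,label_b Group labels recorded in the result.
#' @return An object of class `"group_comparison"`: list with
#'   `mean_diff_dage`, `rank_test_p`, `n_a`, `n_b`, labels.
#' @export
compare_groups <- function(metrics_a, metrics_b,
                           label_a = "a", label_b = "b") {
  for (m in list(metrics_a, metrics_b)) {
    check_columns(m, "dage", "compare_groups")
  }
  a <- metrics_a$dage[!is.na(metrics_a$dage)]
  b <- metrics_b$dage[!is.na(metrics_b$dage)]
  if (length(a) < 2L || length(b) < 2L) {
    stop_config("compare_groups: each group needs >= 2 observations")
  }
  wt <- suppressWarnings(stats::wilcox.test(a, b, alternative = "two.sided"))
  structure(list(group_a = label_a, group_b = label_b,
                 mean_diff_dage = mean(a) - mean(b),
                 rank_test_p = wt$p.value,
                 n_a = length(a), n_b = length(b)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(
    "dAge comparison %s (n=%d) vs %s (n=%d): mean diff %.2f y, rank-sum p = %.3g\n",
    x$group_a, x$n_a, x$group_b, x$n_b, x$mean_diff_dage, x$rank_test_p))
  invisible(x)
}

#' Correlate the age ratio with raw biomarkers
#'
#' For each panel biomarker, fits OLS of the age ratio on the raw
#' (untransformed) biomarker values and reports slope, R-squared and the
#' slope p-value, ranked by R-squared. This identifies which modifiable
#' markers carry the aging signal.
#'
#' @param metrics An [aging_metrics()] table.
#' @param cohort Cohort data frame carrying the raw biomarker columns.
#' @param panel Character vector of biomarker columns.
#' @return Data frame `biomarker`, `slope`, `r_squared`, `p_value`, sorted
#'   by decreasing R-squared.
#' @export
correlate_with_ratio <- function(metrics, cohort, panel) {
  check_columns(metrics, c("subject_id", "age_ratio"), "correlate_with_ratio")
  check_columns(cohort, c("subject_id", panel), "correlate_with_ratio")
  idx <- match(metrics$subject_id, cohort$subject_id)
  if (anyNA(idx)) {
    stop_schema("correlate_with_ratio: unmatched subject(s) in metrics")
  }
  rows <- lapply(panel, function(m) {
    x <- cohort[[m]][idx]
    y <- metrics$age_ratio
    ok <- !is.na(x) & !is.na(y)
    if (stats::sd(x[ok]) == 0) {
      warning("correlate_with_ratio: biomarker '", m, "' is constant",
              call. = FALSE)
      return(data.frame(biomarker = m, slope = NA_real_,
                        r_squared = 0, p_value = NA_real_))
    }
    sm <- summary(stats::lm(y[ok] ~ x[ok]))
    data.frame(biomarker = m,
               slope = sm$coefficients[2, 1],
               r_squared = sm$r.squared,
               p_value = sm$coefficients[2, 4])
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$r_squared), , drop = FALSE]
  rownames(out) <- NULL
  out
}
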