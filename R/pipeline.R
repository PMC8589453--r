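#' End-to-end biological-age analysis of a cohort
#'
#' Orchestrates the full analysis on a cohort table containing controls and
#' one or more disease groups: exclusions, a gender-stratified
#' train/held-out split of the controls, preprocessing fitted on the
#' training controls and frozen, biomarker screening, model fitting,
#' out-of-sample biological age for held-out controls and every disease
#' group, aging metrics, and group comparisons. An optional survival stage
#' fits a Cox model of mortality on delta age when `time`/`event` columns
#' are present.
#'
#' @param cohort Data frame with `subject_id`, `ca`, `gender`, `group`
#'   (`"control"` plus disease labels) and the panel biomarkers.
#' @param panel Panel id (see [bioage_panel()]) or character vector of
#'   biomarker columns.
#' @param method `"kdm1"` or `"mlr"`.
#' @param preprocess Fit and apply the [fit_transform_spec()] recipe
#'   (Box-Cox, standardise, winsorise, gender-adjust). Set to `FALSE` when
#'   the table is already on a modelling scale.
#' @param a1c_cutoff,age_bounds Exclusion parameters
#'   (see [apply_exclusions()]); `a1c_cutoff = NULL` skips that rule.
#' @param train_fraction Control fraction used for calibration.
#' @param survival_covariates Covariates for the optional Cox stage.
#' @param seed Integer seed controlling the split.
#' @return An object of class `"bioage_run"`: list with `screen`, `model`,
#'   `metrics` (held-out controls and disease groups pooled),
#'   `comparisons` (one [compare_groups()] per disease group vs held-out
#'   controls), `cox` (or `NULL`), `exclusion_log`, and `manifest`.
#' @export
#' @examples
#' cfg <- cohort_config(n_subjects = 300, seed = 11)
#' cohort <- rbind(simulate_controls(cfg),
#'                 simulate_disease(cohort_config(n_subjects = 150, seed = 12)))
#' run <- run_pipeline(cohort, preprocess = FALSE, seed = 1)
#' run$comparisons[["t2d"]]
run_pipeline <- function(cohort, panel = "kdm8", method = c("kdm1", "mlr"),
                         preprocess = TRUE, a1c_cutoff = 5.7,
                         age_bounds = c(20, 80), train_fraction = 2 / 3,
                         survival_covariates = NULL, seed = NULL) {
  method <- match.arg(method)
  if (length(panel) == 1L && !panel %in% names(cohort)) {
    panel <- bioage_panel(panel)
  }
  check_columns(cohort, c("subject_id", "ca", "gender", "group", panel),
                "run_pipeline")

  cohort <- apply_exclusions(cohort,
                             a1c_cutoff = if (is.null(a1c_cutoff)) Inf
                                          else a1c_cutoff,
                             age_bounds = age_bounds,
                             required = c("ca", "gender", panel))
  exclusion_log <- attr(cohort, "exclusion_log")

  controls <- cohort[cohort$group == "control", , drop = FALSE]
  disease <- cohort[cohort$group != "control", , drop = FALSE]
  if (nrow(controls) < 10L) {
    stop_config("run_pipeline: too few controls after exclusions (",
                nrow(controls), ")")
  }
  split <- train_test_split(controls, train_fraction, seed = seed)

  tspec <- NULL
  if (isTRUE(preprocess)) {
    tspec <- fit_transform_spec(split$train, panel)
    split$train <- apply_transform_spec(tspec, split$train)
    split$test <- apply_transform_spec(tspec, split$test)
    if (nrow(disease)) disease <- apply_transform_spec(tspec, disease)
  }

  screen <- univariate_screen(split$train, panel)
  redundant <- redundancy_check(split$train, panel)
  if (nrow(redundant)) {
    warning("run_pipeline: redundant biomarker pair(s) flagged: ",
            paste(redundant$biomarker_a, redundant$biomarker_b,
                  sep = "~", collapse = ", "), call. = FALSE)
  }

  model <- bioage(split$train, panel = panel, method = method)

  test_metrics <- aging_metrics(predict(model, split$test), split$test)
  metrics <- test_metrics
  comparisons <- list()
  for (g in unique(disease$group)) {
    sub <- disease[disease$group == g, , drop = FALSE]
    gm <- aging_metrics(predict(model, sub), sub)
    metrics <- rbind(metrics, gm)
    comparisons[[g]] <- compare_groups(gm, test_metrics,
                                       label_a = g, label_b = "control")
  }

  cox <- NULL
  if (all(c("time", "event") %in% names(cohort))) {
    surv_data <- metrics
    idx <- match(surv_data$subject_id, cohort$subject_id)
    surv_data$time <- cohort$time[idx]
    surv_data$event <- cohort$event[idx]
    if (!is.null(survival_covariates)) {
      for (cv in survival_covariates) surv_data[[cv]] <- cohort[[cv]][idx]
    }
    cox <- fit_dage_cox(surv_data, predictor = "continuous",
                        covariates = survival_covariates)
  }

  structure(list(
    screen = screen,
    redundancy = redundant,
    transform_spec = tspec,
    model = model,
    metrics = metrics,
    comparisons = comparisons,
    cox = cox,
    exclusion_log = exclusion_log,
    manifest = list(panel = panel, method = method, seed = seed,
                    preprocess = isTRUE(preprocess),
                    train_fraction = train_fraction,
                    n_controls_train = nrow(split$train),
                    n_controls_test = nrow(split$test),
                    n_disease = nrow(disease),
                    package_version = as.character(utils::packageVersion("clinage")))),
    class = "bioage_run")
}

#' @export
print.bioage_run <- function(x, ...) {
  cat("Biological-age pipeline run (", toupper(x$manifest$method), ", panel: ",
      paste(x$manifest$panel, collapse = ", "), ")\n", sep = "")
  cat("  controls: ", x$manifest$n_controls_train, " train / ",
      x$manifest$n_controls_test, " held out; disease rows: ",
      x$manifest$n_disease, "\n", sep = "")
  for (cmp in x$comparisons) print(cmp)
  if (!is.null(x$cox)) print(x$cox)
  invisible(x)
}

#' Write the result bundle of a pipeline run to a directory
#'
#' Emits `metrics.csv`, `screen.csv`, `comparisons.csv` and a JSON
#' `manifest.json` (seeds, panel, stage counts, package version) so a run
#' can be reproduced and audited from its outputs alone.
#'
#' @param run A `"bioage_run"` object.
#' @param dir Output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  stopifnot(inherits(run, "bioage_run"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_cohort(run$metrics, file.path(dir, "metrics.csv"))
  write_cohort(as.data.frame(run$screen), file.path(dir, "screen.csv"))
  cmp <- do.call(rbind, lapply(run$comparisons, function(x) {
    data.frame(group_a = x$group_a, group_b = x$group_b,
               mean_diff_dage = x$mean_diff_dage,
               rank_test_p = x$rank_test_p, n_a = x$n_a, n_b = x$n_b)
  }))
  if (!is.null(cmp)) write_cohort(cmp, file.path(dir, "comparisons.csv"))
  jsonlite::write_json(run$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
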