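#' Describe the generative law of one synthetic biomarker
#'
#' A biomarker is simulated as a linear function of biological age (BA) with
#' additive Gaussian noise: `x = intercept + slope * BA + N(0, noise_sd^2)`.
#' With `transform = "log-normal"` the law applies on the log scale, so the
#' stored column `exp(intercept + slope * BA + noise)` is strictly positive
#' (used for C-reactive protein, whose formula term is `ln(CRP)`).
#'
#' @param name Column name, unique within a panel.
#' @param intercept Value of the (possibly log-scale) marker at BA = 0.
#' @param slope Change per year of BA; any sign.
#' @param noise_sd Residual standard deviation; must be `>= 0`.
#' @param transform `"none"` or `"log-normal"`.
#' @return An object of class `"biomarker_spec"`.
#' @export
#' @examples
#' biomarker_spec("sbp", intercept = 90, slope = 0.6, noise_sd = 5)
biomarker_spec <- function(name, intercept, slope, noise_sd,
                           transform = c("none", "log-normal")) {
  transform <- match.arg(transform)
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop_config("biomarker_spec: `name` must be a non-empty string")
  }
  if (!is.finite(noise_sd) || noise_sd < 0) {
    stop_config("biomarker_spec: `noise_sd` must be >= 0 for '", name, "'")
  }
  if (!is.finite(intercept) || !is.finite(slope)) {
    stop_config("biomarker_spec: non-finite intercept/slope for '", name, "'")
  }
  structure(list(name = name, intercept = intercept, slope = slope,
                 noise_sd = noise_sd, transform = transform),
            class = "biomarker_spec")
}

#' Default generative laws for the eight-biomarker clinical panel
#'
#' Slopes are signed so that markers drift with age in the direction seen in
#' screening tables for non-diabetic adults (creatinine, blood pressure, urea
#' nitrogen, cholesterol, pulse and HbA1c rise; albumin falls). Magnitudes
#' are package defaults chosen to give each marker a clearly detectable but
#' noisy age signal; they are documented in the methods vignette.
#'
#' @param crp Add a log-normal C-reactive protein marker (needed for the
#'   `"kdm8-crp"` panel where CRP replaces HbA1c).
#' @return Named list of [biomarker_spec()] objects.
#' @export
kdm_panel_specs <- function(crp = FALSE) {
  specs <- list(
    biomarker_spec("creatinine",  0.60,  0.006, 0.05),   # mg/dL
    biomarker_spec("albumin",     5.20, -0.012, 0.10),   # g/dL
    biomarker_spec("cholesterol", 140,   1.2,   15),     # mg/dL
    biomarker_spec("bun",         8.0,   0.15,  2.0),    # mg/dL
    biomarker_spec("sbp",         90,    0.6,   5.0),    # mmHg
    biomarker_spec("dbp",         60,    0.15,  5.0),    # mmHg
    biomarker_spec("pulse",       60,    0.12,  5.0),    # beats/min
    biomarker_spec("a1c",         4.0,   0.02,  0.15)    # %
  )
  if (crp) {
    specs <- c(specs, list(
      biomarker_spec("crp", -1.8, 0.015, 0.35, transform = "log-normal")))
  }
  names(specs) <- vapply(specs, `[[`, "", "name")
  specs
}

#' Default generative laws for the nine-marker phenotypic-age panel
#'
#' The panel uses Levine units (glucose mmol/L, albumin g/L, creatinine
#' umol/L, CRP mg/dL, lymphocyte %, MCV fL, RDW %, ALP U/L, WBC 1000
#' cells/uL). Because the phenotypic-age formula as printed applies
#' `ln(1 - xb)` to the linear predictor directly, `xb` must stay inside
#' (0, 1); the intercepts and slopes here are calibrated for that domain
#' (xb runs from about 0.32 at age 20 to 0.68 at age 80) rather than for
#' population reference ranges. See the methods vignette.
#'
#' @return Named list of [biomarker_spec()] objects.
#' @export
phage_panel_specs <- function() {
  specs <- list(
    biomarker_spec("albumin",          0,      0.8,   0.5),  # g/L
    biomarker_spec("creatinine",       150,    0.4,   2.5),  # umol/L
    biomarker_spec("glucose",          6.0,    0.015, 0.15), # mmol/L
    biomarker_spec("crp",              0.2,    0.012, 0.15,  # mg/dL, log law
                   transform = "log-normal"),
    biomarker_spec("lymphocyte_pct",   5,      0.5,   0.75),
    biomarker_spec("mcv",              140,   -0.35,  0.5),  # fL
    biomarker_spec("rdw",              40.916, -0.115, 0.1), # %
    biomarker_spec("alp",              300,    0.4,   4),    # U/L
    biomarker_spec("wbc",              10,     0.01,  0.25)  # 1000 cells/uL
  )
  names(specs) <- vapply(specs, `[[`, "", "name")
  specs
}

#' Configuration of a synthetic cohort
#'
#' Encodes the generative model shared by every simulation entry point:
#' chronological age (CA) uniform over `age_range`, biological age
#' `BA = CA + N(0, s_ba^2)` plus `group_shift` in disease groups, and each
#' biomarker linear in BA per its [biomarker_spec()]. Missing cells are
#' masked completely at random; outlier cells are multiplied by a factor
#' drawn from `outlier_factors` (giving winsorisation something to shrink).
#'
#' @param n_subjects Number of rows; `>= 1`.
#' @param age_range Two increasing age bounds in years (default 20-80).
#' @param female_fraction Proportion of females in `[0, 1]`.
#' @param specs List of [biomarker_spec()]s; names must be unique.
#' @param s_ba Standard deviation in years of the individual BA - CA noise.
#' @param group_shift Years of BA acceleration added in disease groups
#'   (default 12, the magnitude reported for type-2 diabetes).
#' @param missing_rate,outlier_rate Per-cell probabilities in `[0, 1]`.
#' @param outlier_factors Multipliers sampled for outlier cells.
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @return An object of class `"cohort_config"`.
#' @export
#' @examples
#' cfg <- cohort_config(n_subjects = 100, seed = 1)
#' head(simulate_controls(cfg))
cohort_config <- function(n_subjects = 2000,
                          age_range = c(20, 80),
                          female_fraction = 0.5,
                          specs = kdm_panel_specs(),
                          s_ba = 5,
                          group_shift = 12,
                          missing_rate = 0,
                          outlier_rate = 0,
                          outlier_factors = c(3, 5),
                          seed = NULL) {
  if (!is.numeric(n_subjects) || length(n_subjects) != 1L || n_subjects < 1) {
    stop_config("cohort_config: `n_subjects` must be >= 1")
  }
  if (length(age_range) != 2L || !all(is.finite(age_range)) ||
      age_range[1] >= age_range[2]) {
    stop_config("cohort_config: `age_range` must be two increasing values")
  }
  for (fld in c("female_fraction", "missing_rate", "outlier_rate")) {
    v <- get(fld)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      stop_config("cohort_config: `", fld, "` must lie in [0, 1]")
    }
  }
  if (!is.numeric(s_ba) || length(s_ba) != 1L || !is.finite(s_ba) || s_ba < 0) {
    stop_config("cohort_config: `s_ba` must be >= 0")
  }
  if (!all(vapply(specs, inherits, TRUE, "biomarker_spec"))) {
    stop_config("cohort_config: `specs` must be a list of biomarker_spec objects")
  }
  nm <- vapply(specs, `[[`, "", "name")
  if (anyDuplicated(nm)) {
    stop_config("cohort_config: duplicated biomarker name(s): ",
                paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  names(specs) <- nm
  structure(list(n_subjects = as.integer(n_subjects), age_range = age_range,
                 female_fraction = female_fraction, specs = specs,
                 s_ba = s_ba, group_shift = group_shift,
                 missing_rate = missing_rate, outlier_rate = outlier_rate,
                 outlier_factors = outlier_factors, seed = seed),
            class = "cohort_config")
}

simulate_cohort_impl <- function(config, shift, label, id_prefix = "S") {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, {
    n <- config$n_subjects
    ca <- stats::runif(n, config$age_range[1], config$age_range[2])
    gender <- ifelse(stats::runif(n) < config$female_fraction,
                     "female", "male")
    true_ba <- ca + stats::rnorm(n, 0, config$s_ba) + shift
    out <- data.frame(
      subject_id = sprintf("%s%05d", id_prefix, seq_len(n)),
      ca = ca, gender = gender, group = label,
      stringsAsFactors = FALSE)
    for (sp in config$specs) {
      x <- sp$intercept + sp$slope * true_ba + stats::rnorm(n, 0, sp$noise_sd)
      if (sp$transform == "log-normal") x <- exp(x)
      out[[sp$name]] <- x
    }
    marker_cols <- names(config$specs)
    if (config$outlier_rate > 0) {
      for (m in marker_cols) {
        hit <- stats::runif(n) < config$outlier_rate
        if (any(hit)) {
          fac <- sample(config$outlier_factors, sum(hit), replace = TRUE)
          out[[m]][hit] <- out[[m]][hit] * fac
        }
      }
    }
    if (config$missing_rate > 0) {
      for (m in marker_cols) {
        out[[m]][stats::runif(n) < config$missing_rate] <- NA_real_
      }
    }
    out$true_ba <- true_ba
    out$true_dage <- true_ba - ca
    out
  })
}

#' Simulate a control cohort under the Klemera-Doubal presumptions
#'
#' Controls have `BA = CA + N(0, s_ba^2)` (no group shift) and every
#' biomarker linear in BA. Hidden columns `true_ba` and `true_dage` are
#' retained so parameter recovery can be checked downstream.
#'
#' @param config A [cohort_config()].
#' @return A data frame (one row per subject) with `subject_id`, `ca`,
#'   `gender`, `group`, the biomarker columns, `true_ba` and `true_dage`.
#' @export
simulate_controls <- function(config) {
  simulate_cohort_impl(config, shift = 0, label = "control", id_prefix = "C")
}

#' Simulate a disease group with accelerated biological age
#'
#' Identical to [simulate_controls()] except that `config$group_shift` years
#' are added to every subject's true BA, emulating the group-level BA
#' increase observed in diabetes cohorts.
#'
#' @param config A [cohort_config()]; `group_shift` may be any sign.
#' @param label Group label attached to the rows (e.g. `"t2d"`).
#' @return Data frame as in [simulate_controls()].
#' @export
simulate_disease <- function(config, label = "t2d") {
  if (!is.numeric(config$group_shift) || !is.finite(config$group_shift)) {
    stop_config("simulate_disease: `group_shift` must be a finite number")
  }
  simulate_cohort_impl(config, shift = config$group_shift, label = label,
                       id_prefix = "D")
}

#' Simulate a cohort carrying the nine phenotypic-age markers
#'
#' As [simulate_controls()], but validates that the panel covers all nine
#' Levine markers (in Levine units) and that CRP follows a log-normal law so
#' the `ln(CRP)` formula term is defined for every row.
#'
#' @param config A [cohort_config()] whose `specs` cover the nine markers;
#'   defaults to [phage_panel_specs()] with `s_ba = 1` (the narrow log
#'   domain of the printed formula tolerates little BA noise; see the
#'   methods vignette).
#' @return Data frame as in [simulate_controls()].
#' @export
simulate_phage_cohort <- function(config = cohort_config(specs = phage_panel_specs(),
                                                         s_ba = 1)) {
  need <- phage_marker_names()
  absent <- setdiff(need, names(config$specs))
  if (length(absent)) {
    stop_config("simulate_phage_cohort: panel is missing phenotypic-age marker(s): ",
                paste(absent, collapse = ", "))
  }
  if (config$specs[["crp"]]$transform != "log-normal") {
    stop_config("simulate_phage_cohort: `crp` must use the log-normal law")
  }
  simulate_cohort_impl(config, shift = 0, label = "control", id_prefix = "P")
}

#' Attach simulated survival outcomes driven by delta age
#'
#' Draws exponential time-to-event with subject hazard
#' `baseline_hazard * exp(log_hr_per_year * true_dage)` and applies
#' administrative censoring at `censor_time`, so a downstream Cox
#' proportional-hazards fit should recover `exp(log_hr_per_year)` per year
#' of delta age.
#'
#' @param cohort A simulated cohort carrying `true_dage`.
#' @param baseline_hazard Events per year at delta age 0; must be `> 0`.
#' @param log_hr_per_year Log hazard ratio per year of delta age.
#' @param censor_time Administrative censoring horizon in years.
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @return The cohort with `time` (years) and `event` (1 death, 0 censored).
#' @export
simulate_survival <- function(cohort, baseline_hazard = 0.02,
                              log_hr_per_year = log(1.05),
                              censor_time = 10, seed = NULL) {
  if (!"true_dage" %in% names(cohort)) {
    stop_config("simulate_survival: cohort lacks `true_dage`")
  }
  if (!is.numeric(baseline_hazard) || baseline_hazard <= 0) {
    stop_config("simulate_survival: `baseline_hazard` must be > 0")
  }
  if (censor_time < 0) stop_config("simulate_survival: `censor_time` must be >= 0")
  with_seed(seed, {
    rate <- baseline_hazard * exp(log_hr_per_year * cohort$true_dage)
    t_event <- stats::rexp(nrow(cohort), rate = rate)
    cohort$time <- pmin(t_event, censor_time)
    cohort$event <- as.integer(t_event <= censor_time)
    cohort
  })
}

phage_marker_names <- function() {
  c("albumin", "creatinine", "glucose", "crp", "lymphocyte_pct",
    "mcv", "rdw", "alp", "wbc")
}
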