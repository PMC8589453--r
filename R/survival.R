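#' Cox proportional-hazards model for delta age and mortality
#'
#' Fits a Cox model of time-to-death on delta age, either as a continuous
#' per-year predictor or dichotomized at the in-sample median (the "high"
#' arm being delta age at or above the median). Tied event times use the
#' Efron approximation; confidence intervals are Wald intervals on the
#' log-hazard scale. Optional adjustment covariates and one interaction
#' term (predictor x covariate) are supported, mirroring trial-arm
#' adjustment in mortality validation analyses.
#'
#' @param data Data frame with `time` (years), `event` (1 = death,
#'   0 = censored), the delta-age column, and any covariates.
#' @param predictor `"continuous"` or `"dichotomized"` (at the median).
#' @param covariates Character vector of adjustment columns, or `NULL`.
#' @param interaction_with Optional single covariate name; adds a
#'   `predictor:covariate` interaction whose p-value is reported.
#' @param dage_col,time_col,event_col Column names.
#' @return An object of class `"dage_cox"`: list with `hazard_ratio`,
#'   `ci95`, `p_value`, `n`, `events`, `predictor`, `cut` (median used, for
#'   dichotomized mode), `interaction_p` (or `NA`), and the underlying
#'   `survival::coxph` fit as `fit`.
#' @export
#' @examples
#' cohort <- simulate_controls(cohort_config(n_subjects = 500, seed = 3))
#' surv <- simulate_survival(cohort, 0.03, log(1.06), 10, seed = 4)
#' surv$dage <- surv$true_dage
#' fit_dage_cox(surv, predictor = "continuous")
fit_dage_cox <- function(data, predictor = c("continuous", "dichotomized"),
                         covariates = NULL, interaction_with = NULL,
                         dage_col = "dage", time_col = "time",
                         event_col = "event") {
  predictor <- match.arg(predictor)
  check_columns(data, c(dage_col, time_col, event_col, covariates,
                        interaction_with), "fit_dage_cox")
  used <- c(dage_col, time_col, event_col, covariates, interaction_with)
  if (anyNA(data[, used, drop = FALSE])) {
    stop_config("fit_dage_cox: missing values in model columns")
  }
  events <- sum(data[[event_col]])
  if (events < 2L) {
    stop_config("fit_dage_cox: need >= 2 events, got ", events)
  }
  cut <- NA_real_
  if (predictor == "dichotomized") {
    cut <- stats::median(data[[dage_col]])
    data$.pred <- as.integer(data[[dage_col]] >= cut)
  } else {
    data$.pred <- data[[dage_col]]
  }
  rhs <- ".pred"
  if (length(covariates)) rhs <- c(rhs, covariates)
  if (!is.null(interaction_with)) {
    rhs <- c(rhs, paste0(".pred:", interaction_with))
  }
  fml <- stats::as.formula(paste0(
    "survival::Surv(", time_col, ", ", event_col, ") ~ ",
    paste(rhs, collapse = " + ")))
  fit <- survival::coxph(fml, data = data, ties = "efron",
                         control = survival::coxph.control(iter.max = 100,
                                                           eps = 1e-10))
  sm <- summary(fit)
  beta <- sm$coefficients[".pred", "coef"]
  se <- sm$coefficients[".pred", "se(coef)"]
  interaction_p <- NA_real_
  if (!is.null(interaction_with)) {
    irow <- grep("^\\.pred:", rownames(sm$coefficients))
    interaction_p <- sm$coefficients[irow, "Pr(>|z|)"]
  }
  structure(list(
    predictor = predictor,
    cut = cut,
    hazard_ratio = exp(beta),
    ci95 = exp(beta + c(-1, 1) * stats::qnorm(0.975) * se),
    p_value = sm$coefficients[".pred", "Pr(>|z|)"],
    n = nrow(data),
    events = events,
    covariates = covariates %||% character(),
    interaction_p = interaction_p,
    fit = fit), class = "dage_cox")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.dage_cox <- function(x, ...) {
  lab <- if (x$predictor == "continuous") "per year of dAge"
         else sprintf(">= median (%.2f y) vs below", x$cut)
  cat(sprintf("Cox PH: HR %.3f (95%% CI %.3f-%.3f), p = %.3g, %s\n",
              x$hazard_ratio, x$ci95[1], x$ci95[2], x$p_value, lab))
  cat(sprintf("  n = %d, events = %d", x$n, x$events))
  if (length(x$covariates)) {
    cat(", adjusted for ", paste(x$covariates, collapse = ", "), sep = "")
  }
  cat("\n")
  if (!is.na(x$interaction_p)) {
    cat(sprintf("  interaction p = %.3g\n", x$interaction_p))
  }
  invisible(x)
}

#' Kaplan-Meier survival curves by group
#'
#' Product-limit estimates per group; curves start at probability 1 and
#' censored subjects leave the risk set without a drop.
#'
#' @param data Data frame with `time` and `event` columns.
#' @param groups Vector of group labels, one per row.
#' @param time_col,event_col Column names.
#' @return An object of class `"km_curves"`: data frame with `group`,
#'   `time`, `surv`, `n_risk`, `n_event`.
#' @export
km_curve <- function(data, groups, time_col = "time", event_col = "event") {
  check_columns(data, c(time_col, event_col), "km_curve")
  if (length(groups) != nrow(data)) {
    stop_config("km_curve: `groups` must have one label per row")
  }
  df <- data.frame(time = data[[time_col]], event = data[[event_col]],
                   group = as.character(groups))
  sf <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  strata <- if (is.null(sf$strata)) {
    rep(unique(df$group), length(sf$time))
  } else {
    rep(sub("^group=", "", names(sf$strata)), sf$strata)
  }
  out <- data.frame(group = strata, time = sf$time, surv = sf$surv,
                    n_risk = sf$n.risk, n_event = sf$n.event,
                    stringsAsFactors = FALSE)
  class(out) <- c("km_curves", "data.frame")
  out
}

#' @export
plot.km_curves <- function(x, xlab = "Years", ylab = "Survival", ...) {
  grp <- unique(x$group)
  plot(NULL, xlim = c(0, max(x$time)), ylim = c(0, 1),
       xlab = xlab, ylab = ylab, ...)
  for (i in seq_along(grp)) {
    sub <- x[x$group == grp[i], ]
    graphics::lines(stats::stepfun(sub$time, c(1, sub$surv)),
                    do.points = FALSE, col = i)
  }
  graphics::legend("bottomleft", legend = grp, col = seq_along(grp), lty = 1)
  invisible(x)
}
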