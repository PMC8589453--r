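#' Box-Cox power transform with profile-likelihood lambda
#'
#' Transforms strictly positive values by `(x^lambda - 1) / lambda`
#' (`ln(x)` at `lambda = 0`). When `lambda` is `NULL` it is chosen by
#' maximising the profile log-likelihood over `[-5, 5]` (coarse grid
#' followed by golden-section refinement via [stats::optimize()], tolerance
#' `1e-4`).
#'
#' @param x Strictly positive numeric vector of length `>= 10` (any length
#'   is accepted when `lambda` is supplied).
#' @param lambda Fixed exponent, or `NULL` to estimate it.
#' @param name Biomarker name used in error messages.
#' @return List with `values` (transformed vector) and `lambda`.
#' @export
#' @examples
#' box_cox(c(1, 2, 3, 4, 5, 10), lambda = 0)$values  # log transform
box_cox <- function(x, lambda = NULL, name = "biomarker") {
  x_ok <- x[!is.na(x)]
  if (any(x_ok <= 0)) {
    stop_domain("box_cox: '", name, "' has non-positive values; ",
                "Box-Cox requires a strictly positive vector")
  }
  if (is.null(lambda)) {
    if (length(x_ok) < 10L) {
      stop_config("box_cox: need >= 10 observations to estimate lambda for '",
                  name, "'")
    }
    ll <- function(l) boxcox_loglik(x_ok, l)
    grid <- seq(-5, 5, by = 0.1)
    best <- grid[which.max(vapply(grid, ll, 1))]
    lo <- max(-5, best - 0.1)
    hi <- min(5, best + 0.1)
    lambda <- stats::optimize(ll, c(lo, hi), maximum = TRUE, tol = 1e-4)$maximum
  }
  values <- if (abs(lambda) < 1e-12) log(x) else (x^lambda - 1) / lambda
  list(values = values, lambda = lambda)
}

# Profile log-likelihood of the Box-Cox model (normal errors, MLE variance).
boxcox_loglik <- function(x, lambda) {
  n <- length(x)
  z <- if (abs(lambda) < 1e-12) log(x) else (x^lambda - 1) / lambda
  s2 <- mean((z - mean(z))^2)
  -n / 2 * log(s2) + (lambda - 1) * sum(log(x))
}

#' Decide whether Box-Cox can be applied to a vector
#'
#' The power transform is undefined at non-positive values; rather than
#' shifting such a marker, the policy is to skip its transformation (as is
#' done for a blood-pressure column containing a zero reading that is
#' already approximately normal).
#'
#' @param x Numeric vector.
#' @return `"transform"` if all non-missing values are `> 0`, else `"skip"`.
#' @export
box_cox_decision <- function(x) {
  if (any(x[!is.na(x)] <= 0)) "skip" else "transform"
}

#' Winsorize a vector at percentile bounds
#'
#' Values below the lower-percentile order statistic are raised to it, and
#' symmetrically above the upper one. Bounds are order statistics of the
#' input (inverse-ECDF quantiles), which makes the operation idempotent.
#'
#' @param x Numeric vector of length `>= 3`.
#' @param limits Lower and upper percentile as proportions, default
#'   `c(0.01, 0.99)`.
#' @return The winsorized vector.
#' @export
winsorize <- function(x, limits = c(0.01, 0.99)) {
  if (length(limits) != 2L || any(!is.finite(limits)) ||
      limits[1] < 0 || limits[2] > 1 || limits[1] >= limits[2]) {
    stop_config("winsorize: `limits` must satisfy 0 <= lower < upper <= 1")
  }
  if (sum(!is.na(x)) < 3L) stop_config("winsorize: need >= 3 observations")
  qs <- stats::quantile(x, probs = limits, na.rm = TRUE, type = 1, names = FALSE)
  pmin(pmax(x, qs[1]), qs[2])
}

#' Remove the gender mean difference from a biomarker
#'
#' Regresses the values on a gender indicator and returns the residuals plus
#' the grand mean, so per-gender means are equalised while the overall level
#' is preserved.
#'
#' @param x Numeric vector.
#' @param gender Vector of gender labels; both genders must be present.
#' @return Adjusted numeric vector.
#' @export
gender_adjust <- function(x, gender) {
  ok <- !is.na(x) & !is.na(gender)
  if (length(unique(gender[ok])) < 2L) {
    stop_config("gender_adjust: both genders must be present")
  }
  out <- x
  fit <- stats::lm(x[ok] ~ factor(gender[ok]))
  out[ok] <- stats::residuals(fit) + mean(x[ok])
  out
}

#' Fit the biomarker preprocessing recipe on training controls
#'
#' Learns, per biomarker and in this order: a Box-Cox exponent (skipped for
#' markers with non-positive values), standardisation mean/sd, winsor
#' bounds on the standardised scale, and per-gender offsets. The fitted
#' recipe is frozen: applying it to held-out or disease-group data reuses
#' the training parameters so no information leaks out of the training set.
#'
#' @param train Training-control data frame with `gender` and the panel.
#' @param panel Character vector of biomarker column names.
#' @param winsor_limits Percentile bounds passed to [winsorize()].
#' @param use_box_cox,use_gender_adjust Toggles for the respective steps.
#' @return An object of class `"transform_spec"`.
#' @export
fit_transform_spec <- function(train, panel, winsor_limits = c(0.01, 0.99),
                               use_box_cox = TRUE, use_gender_adjust = TRUE) {
  check_columns(train, c("gender", panel), "fit_transform_spec")
  per <- list()
  for (m in panel) {
    x <- train[[m]]
    lambda <- NA_real_
    if (use_box_cox && box_cox_decision(x) == "transform") {
      bc <- box_cox(x, name = m)
      x <- bc$values
      lambda <- bc$lambda
    }
    mu <- mean(x, na.rm = TRUE)
    sdev <- stats::sd(x, na.rm = TRUE)
    if (!is.finite(sdev) || sdev <= 0) {
      stop_config("fit_transform_spec: biomarker '", m, "' has zero variance")
    }
    z <- (x - mu) / sdev
    bounds <- stats::quantile(z, probs = winsor_limits, na.rm = TRUE,
                              type = 1, names = FALSE)
    z <- pmin(pmax(z, bounds[1]), bounds[2])
    offsets <- c(male = 0, female = 0)
    if (use_gender_adjust) {
      gm <- tapply(z, train$gender, mean, na.rm = TRUE)
      offsets <- gm - mean(z, na.rm = TRUE)
    }
    per[[m]] <- list(lambda = lambda, mean = mu, sd = sdev,
                     winsor_bounds = bounds, gender_offsets = offsets)
  }
  structure(list(panel = panel, winsor_limits = winsor_limits,
                 use_gender_adjust = use_gender_adjust, per_biomarker = per),
            class = "transform_spec")
}

#' Apply a frozen preprocessing recipe to new data
#'
#' @param spec A `"transform_spec"` from [fit_transform_spec()].
#' @param data Data frame carrying the recipe's biomarker panel.
#' @return `data` with the panel columns replaced by their preprocessed
#'   values.
#' @export
apply_transform_spec <- function(spec, data) {
  stopifnot(inherits(spec, "transform_spec"))
  check_columns(data, spec$panel, "apply_transform_spec")
  for (m in spec$panel) {
    p <- spec$per_biomarker[[m]]
    x <- data[[m]]
    if (!is.na(p$lambda)) {
      x <- box_cox(x, lambda = p$lambda, name = m)$values
    }
    z <- (x - p$mean) / p$sd
    z <- pmin(pmax(z, p$winsor_bounds[1]), p$winsor_bounds[2])
    if (spec$use_gender_adjust) {
      off <- p$gender_offsets[as.character(data$gender)]
      off[is.na(off)] <- 0
      z <- z - off
    }
    data[[m]] <- as.numeric(z)
  }
  data
}

#' Screen biomarkers for association with chronological age
#'
#' For each panel biomarker, fits a univariate ordinary least-squares
#' regression of the (preprocessed) biomarker on chronological age and
#' records the slope-test p-value and R-squared. A biomarker is selected
#' when `p < p_threshold`; an advisory age-collinearity flag is raised when
#' its R-squared exceeds `paradox_threshold` (such markers are retained,
#' merely flagged, since over-tight coupling to CA defeats the purpose of a
#' biological-age panel).
#'
#' @param data Preprocessed cohort data frame.
#' @param panel Character vector of biomarker columns.
#' @param ca_col Chronological-age column name.
#' @param p_threshold Selection threshold on the slope p-value.
#' @param paradox_threshold R-squared above which the advisory flag is set.
#' @return An object of class `"screen_report"`: data frame with one row
#'   per biomarker (`biomarker`, `p_value`, `r_squared`, `selected`,
#'   `ca_paradox`).
#' @export
univariate_screen <- function(data, panel, ca_col = "ca",
                              p_threshold = 0.05, paradox_threshold = 0.32) {
  check_columns(data, c(ca_col, panel), "univariate_screen")
  rows <- lapply(panel, function(m) {
    x <- data[[m]]
    ok <- !is.na(x) & !is.na(data[[ca_col]])
    if (stats::sd(x[ok]) == 0) {
      warning("univariate_screen: biomarker '", m, "' has zero variance",
              call. = FALSE)
      return(data.frame(biomarker = m, p_value = NA_real_,
                        r_squared = 0, selected = FALSE, ca_paradox = FALSE))
    }
    fit <- stats::lm(x[ok] ~ data[[ca_col]][ok])
    sm <- summary(fit)
    p <- sm$coefficients[2, 4]
    r2 <- sm$r.squared
    data.frame(biomarker = m, p_value = p, r_squared = r2,
               selected = p < p_threshold,
               ca_paradox = ca_paradox_flag(r2, paradox_threshold))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("screen_report", "data.frame")
  attr(out, "p_threshold") <- p_threshold
  attr(out, "paradox_threshold") <- paradox_threshold
  out
}

#' Flag biomarker pairs that are mutually redundant
#'
#' Computes all pairwise Pearson correlations within the panel and flags
#' pairs whose absolute correlation strictly exceeds the cutoff (a pair at
#' exactly the cutoff is not flagged). Flagging is advisory; callers decide
#' whether to drop the member with the weaker age signal.
#'
#' @param data Cohort data frame.
#' @param panel Character vector of `>= 2` biomarker columns.
#' @param r_cutoff Absolute-correlation cutoff, default 0.75.
#' @return Data frame of flagged pairs (`biomarker_a`, `biomarker_b`,
#'   `correlation`); zero rows when none exceed the cutoff.
#' @export
redundancy_check <- function(data, panel, r_cutoff = 0.75) {
  check_columns(data, panel, "redundancy_check")
  if (length(panel) < 2L) {
    stop_config("redundancy_check: need at least two biomarkers")
  }
  cm <- stats::cor(data[, panel, drop = FALSE], use = "pairwise.complete.obs")
  out <- data.frame(biomarker_a = character(), biomarker_b = character(),
                    correlation = numeric())
  for (i in seq_len(length(panel) - 1L)) {
    for (j in seq((i + 1L), length(panel))) {
      if (is.finite(cm[i, j]) && abs(cm[i, j]) > r_cutoff) {
        out <- rbind(out, data.frame(biomarker_a = panel[i],
                                     biomarker_b = panel[j],
                                     correlation = cm[i, j]))
      }
    }
  }
  out
}

#' Advisory flag for biomarkers too collinear with chronological age
#'
#' A biomarker whose univariate R-squared against CA strictly exceeds the
#' threshold is flagged as failing to mitigate the "CA paradox": it mostly
#' restates calendar age instead of adding physiological information.
#' Flagged markers are conventionally retained.
#'
#' @param r_squared R-squared value(s) in `[0, 1]`.
#' @param threshold Flag threshold, default 0.32.
#' @return Logical vector.
#' @export
#' @examples
#' ca_paradox_flag(c(0.36, 0.26, 0.32))
ca_paradox_flag <- function(r_squared, threshold = 0.32) {
  if (any(!is.finite(r_squared) | r_squared < 0 | r_squared > 1)) {
    stop_domain("ca_paradox_flag: `r_squared` must lie in [0, 1]")
  }
  r_squared > threshold
}
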