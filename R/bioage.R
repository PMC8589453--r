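#' Fit a biological-age estimator on control subjects
#'
#' Trains one of two biological-age (BA) models per gender on a control
#' cohort:
#' \describe{
#'   \item{`"kdm1"`}{the Klemera-Doubal method. Each biomarker is regressed
#'     on chronological age (CA) by OLS, giving a calibration triple
#'     `(q_j, k_j, s_j)`: intercept, slope, and residual standard deviation
#'     (root mean square with denominator `n - 2`). Prediction then inverts
#'     the biomarker laws: `BA = sum_j (x_j - q_j) k_j / s_j^2 /
#'     sum_j k_j^2 / s_j^2`, the weighted-least-squares minimiser of
#'     `sum_j ((x_j - q_j - k_j BA) / s_j)^2`. CA is not an input to the
#'     prediction.}
#'   \item{`"mlr"`}{multiple linear regression of CA on the panel,
#'     `BA_i = b_0 + sum_j b_j x_ji`. Being a direct regression it shrinks
#'     predictions toward the mean training age, so its BA-on-CA slope is
#'     below the KDM one on noisy data.}
#' }
#'
#' @param data Control data frame with `ca`, `gender` and the panel columns,
#'   already preprocessed if a [fit_transform_spec()] recipe is in use.
#' @param panel Character vector of biomarker columns (default the `kdm8`
#'   built-in, see [bioage_panel()]).
#' @param method `"kdm1"` or `"mlr"`.
#' @param ca_col,gender_col Column names for age and gender.
#' @return An object of class `"bioage"` with `coef`, `print`, `summary`
#'   and `predict` methods.
#' @seealso [predict.bioage()], [phenotypic_age()]
#' @export
#' @examples
#' cohort <- simulate_controls(cohort_config(n_subjects = 400, seed = 7))
#' fit <- bioage(cohort, method = "kdm1")
#' head(predict(fit, cohort))
bioage <- function(data, panel = bioage_panel("kdm8"),
                   method = c("kdm1", "mlr"),
                   ca_col = "ca", gender_col = "gender") {
  method <- match.arg(method)
  check_columns(data, c(ca_col, gender_col, panel), "bioage")
  genders <- sort(unique(as.character(data[[gender_col]])))
  if (!length(genders)) stop_config("bioage: no rows to train on")

  models <- lapply(genders, function(g) {
    sub <- data[data[[gender_col]] == g, , drop = FALSE]
    sub <- sub[stats::complete.cases(sub[, c(ca_col, panel)]), , drop = FALSE]
    if (nrow(sub) < length(panel) + 2L) {
      stop_config("bioage: too few complete rows (", nrow(sub),
                  ") to train the ", g, " model")
    }
    if (method == "kdm1") fit_kdm_gender(sub, panel, ca_col)
    else fit_mlr_gender(sub, panel, ca_col)
  })
  names(models) <- genders

  structure(list(method = method, panel = panel, genders = genders,
                 models = models, ca_col = ca_col, gender_col = gender_col,
                 n_train = nrow(data)),
            class = "bioage")
}

# KDM calibration for one gender: per-biomarker OLS of x_j on CA.
fit_kdm_gender <- function(sub, panel, ca_col) {
  ca <- sub[[ca_col]]
  coefs <- lapply(panel, function(m) {
    x <- sub[[m]]
    if (stats::sd(x) == 0) {
      stop_config("bioage: biomarker '", m, "' is constant in training data")
    }
    fit <- stats::lm(x ~ ca)
    res <- stats::residuals(fit)
    s <- sqrt(sum(res^2) / (length(res) - 2))
    if (s <= 0) s <- .Machine$double.eps  # exact interpolation limit
    data.frame(biomarker = m,
               q = unname(stats::coef(fit)[1]),
               k = unname(stats::coef(fit)[2]),
               s = s)
  })
  coefs <- do.call(rbind, coefs)
  if (all(coefs$k == 0)) {
    stop_config("bioage: all biomarker slopes are zero; KDM is undefined")
  }
  list(coefficients = coefs, n = nrow(sub))
}

# MLR calibration for one gender: OLS of CA on the panel.
fit_mlr_gender <- function(sub, panel, ca_col) {
  X <- as.matrix(sub[, panel, drop = FALSE])
  qrX <- qr(cbind(1, X))
  if (qrX$rank < ncol(X) + 1L) {
    dropped <- c("(Intercept)", panel)[qrX$pivot[-seq_len(qrX$rank)]]
    stop_config("bioage: rank-deficient design; collinear column(s): ",
                paste(dropped, collapse = ", "))
  }
  fit <- stats::lm(sub[[ca_col]] ~ X)
  b <- stats::coef(fit)
  names(b) <- c("(Intercept)", panel)
  list(coefficients = b, n = nrow(sub))
}

#' Predict biological age for new subjects
#'
#' Applies the gender-matched sub-model to each subject. Subjects must carry
#' every panel biomarker (preprocessed with the same frozen recipe as the
#' training data, if one was used) and a gender present in the trained
#' model; either violation is an error.
#'
#' @param object A fitted [bioage()] model.
#' @param newdata Data frame of subjects.
#' @param ... Unused.
#' @return A data frame (one row per subject): `subject_id`, `estimator`,
#'   `ba`, `gender`, plus a `panel` attribute recording provenance.
#' @export
predict.bioage <- function(object, newdata, ...) {
  check_columns(newdata, c(object$gender_col, object$panel), "predict.bioage")
  g <- as.character(newdata[[object$gender_col]])
  unknown <- setdiff(unique(g), object$genders)
  if (length(unknown)) {
    stop_config("predict.bioage: no trained sub-model for gender(s): ",
                paste(unknown, collapse = ", "),
                " (models are fit for each gender separately)")
  }
  X <- as.matrix(newdata[, object$panel, drop = FALSE])
  if (anyNA(X)) {
    stop_config("predict.bioage: missing biomarker values; ",
                "apply exclusions before prediction")
  }
  ba <- numeric(nrow(newdata))
  for (gg in object$genders) {
    idx <- which(g == gg)
    if (!length(idx)) next
    mod <- object$models[[gg]]
    if (object$method == "kdm1") {
      cf <- mod$coefficients
      w <- cf$k / cf$s^2                       # per-biomarker weight k/s^2
      denom <- sum(cf$k^2 / cf$s^2)
      centered <- sweep(X[idx, , drop = FALSE], 2, cf$q)
      ba[idx] <- as.numeric(centered %*% w) / denom
    } else {
      b <- mod$coefficients
      ba[idx] <- b[1] + as.numeric(X[idx, , drop = FALSE] %*% b[-1])
    }
  }
  out <- data.frame(
    subject_id = if ("subject_id" %in% names(newdata)) newdata$subject_id
                 else sprintf("row%05d", seq_len(nrow(newdata))),
    estimator = object$method,
    ba = ba,
    gender = g,
    stringsAsFactors = FALSE)
  attr(out, "panel") <- object$panel
  out
}

#' @export
coef.bioage <- function(object, ...) {
  if (object$method == "kdm1") {
    out <- do.call(rbind, lapply(object$genders, function(g) {
      cbind(gender = g, object$models[[g]]$coefficients)
    }))
    rownames(out) <- NULL
    out
  } else {
    do.call(rbind, lapply(object$models, `[[`, "coefficients"))
  }
}

#' @export
print.bioage <- function(x, ...) {
  cat("Biological-age model (", toupper(x$method), ")\n", sep = "")
  cat("  panel  : ", paste(x$panel, collapse = ", "), "\n", sep = "")
  ns <- vapply(x$models, `[[`, 1L, "n")
  cat("  trained: ", paste(sprintf("%s (n=%d)", x$genders, ns),
                           collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
summary.bioage <- function(object, ...) {
  print(object)
  cat("\nCoefficients:\n")
  print(coef(object))
  invisible(object)
}
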