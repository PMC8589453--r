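#' Coefficient set of the phenotypic-age formula
#'
#' Phenotypic age maps nine blood biomarkers plus chronological age through
#' a fixed linear predictor `xb` into
#' `PhAge = 141.50 + ln(-0.0053 * ln(1 - xb)) / 0.09165`.
#'
#' Two variants of `xb` are provided:
#' \describe{
#'   \item{`"levine-sign"` (default)}{`xb = -19.907 - 0.0336 albumin +
#'     0.0095 creatinine + 0.0195 glucose + 0.0954 ln(CRP) -
#'     0.0120 lymphocyte% + 0.0268 MCV + 0.3356 RDW + 0.00188 ALP +
#'     0.0554 WBC + 0.0804 CA`, i.e. an additive intercept with a signed
#'     albumin term, following Levine's original coefficient signs.}
#'   \item{`"as-printed"`}{a literal reading in which the leading term is
#'     the product `-19.907 * 0.0336 * albumin`; retained only for fidelity
#'     audits, because it makes `xb` scale-degenerate.}
#' }
#' The outer constants (141.50, 0.0053, 0.09165) are identical in both
#' variants. Units: albumin g/L, creatinine umol/L, glucose mmol/L, CRP
#' mg/dL, lymphocyte %, MCV fL, RDW %, ALP U/L, WBC 1000 cells/uL, CA years.
#'
#' @param variant Which reading of the linear predictor to use.
#' @return An object of class `"phage_spec"`.
#' @export
#' @examples
#' phage_spec()$coefficients[["ca"]]  # 0.0804 per year
phage_spec <- function(variant = c("levine-sign", "as-printed")) {
  variant <- match.arg(variant)
  structure(list(
    variant = variant,
    intercept = -19.907,
    coefficients = c(albumin = -0.0336, creatinine = 0.0095,
                     glucose = 0.0195, log_crp = 0.0954,
                     lymphocyte_pct = -0.0120, mcv = 0.0268,
                     rdw = 0.3356, alp = 0.00188, wbc = 0.0554,
                     ca = 0.0804),
    outer = c(offset = 141.50, inner_scale = 0.0053, denom = 0.09165)),
    class = "phage_spec")
}

#' @export
print.phage_spec <- function(x, ...) {
  cat("Phenotypic-age coefficient set (variant: ", x$variant, ")\n", sep = "")
  print(x$coefficients)
  invisible(x)
}

#' Compute phenotypic age
#'
#' Evaluates the phenotypic-age formula for each subject. The nine markers
#' and chronological age must be present in Levine units (see
#' [unit_convert()] for the common conversions) and CRP must be strictly
#' positive since the formula uses `ln(CRP)`.
#'
#' The printed outer form requires `0 < xb < 1` (so that
#' `-0.0053 * ln(1 - xb) > 0`); subjects outside this domain raise an error
#' naming the offending term, or yield `NA` when
#' `on_domain_error = "na"`.
#'
#' @param data Data frame with columns `albumin`, `creatinine`, `glucose`,
#'   `crp`, `lymphocyte_pct`, `mcv`, `rdw`, `alp`, `wbc` and the CA column.
#' @param spec A [phage_spec()]; its variant is recorded in the output.
#' @param ca_col Chronological-age column name.
#' @param on_domain_error `"error"` (default) or `"na"`.
#' @return Data frame `subject_id`, `estimator` (`"phage"`), `ba`,
#'   `variant`.
#' @export
phenotypic_age <- function(data, spec = phage_spec(), ca_col = "ca",
                           on_domain_error = c("error", "na")) {
  stopifnot(inherits(spec, "phage_spec"))
  on_domain_error <- match.arg(on_domain_error)
  markers <- phage_marker_names()
  absent <- setdiff(c(markers, ca_col), names(data))
  if (length(absent)) {
    stop_schema("phenotypic_age: missing column(s): ",
                paste(absent, collapse = ", "))
  }
  crp <- data$crp
  if (any(!is.na(crp) & crp <= 0)) {
    bad <- which(!is.na(crp) & crp <= 0)
    msg <- paste0("phenotypic_age: ln(CRP) undefined (CRP <= 0) for ",
                  length(bad), " subject(s)")
    if (on_domain_error == "error") stop_domain(msg)
    warning(msg, call. = FALSE)
  }
  co <- spec$coefficients
  albumin_term <- if (spec$variant == "as-printed") {
    # literal product reading of the printed leading term
    spec$intercept * (-co[["albumin"]]) * data$albumin
  } else {
    spec$intercept + co[["albumin"]] * data$albumin
  }
  xb <- albumin_term +
    co[["creatinine"]] * data$creatinine +
    co[["glucose"]] * data$glucose +
    co[["log_crp"]] * suppressWarnings(log(data$crp)) +
    co[["lymphocyte_pct"]] * data$lymphocyte_pct +
    co[["mcv"]] * data$mcv +
    co[["rdw"]] * data$rdw +
    co[["alp"]] * data$alp +
    co[["wbc"]] * data$wbc +
    co[["ca"]] * data[[ca_col]]

  inner <- -spec$outer[["inner_scale"]] * suppressWarnings(log(1 - xb))
  out_of_domain <- !is.na(xb) & (xb >= 1 | inner <= 0)
  if (any(out_of_domain)) {
    msg <- paste0("phenotypic_age: xb outside (0, 1) for ",
                  sum(out_of_domain), " subject(s); ",
                  "ln(-0.0053 * ln(1 - xb)) undefined (first offending xb = ",
                  signif(xb[which(out_of_domain)[1]], 4), ")")
    if (on_domain_error == "error") stop_domain(msg)
    warning(msg, call. = FALSE)
  }
  ba <- rep(NA_real_, length(xb))
  ok <- !is.na(xb) & !out_of_domain
  ba[ok] <- spec$outer[["offset"]] +
    log(inner[ok]) / spec$outer[["denom"]]
  data.frame(
    subject_id = if ("subject_id" %in% names(data)) data$subject_id
                 else sprintf("row%05d", seq_len(nrow(data))),
    estimator = "phage",
    ba = ba,
    variant = spec$variant,
    stringsAsFactors = FALSE)
}

#' Convert biomarker units
#'
#' Exact scalar conversions between the units used by clinical panels and
#' the Levine phenotypic-age units: albumin g/dL to g/L (x10), creatinine
#' mg/dL to umol/L (x88.42), glucose mg/dL to mmol/L (/18.016), and their
#' inverses.
#'
#' @param x Numeric value(s).
#' @param from,to Unit strings, e.g. `"g/dL"`, `"mg/dL"`, `"umol/L"`,
#'   `"mmol/L"`, `"g/L"`.
#' @return Converted values; round-trips return the input to `1e-12`.
#' @export
#' @examples
#' unit_convert(1.0, "mg/dL", "umol/L")  # creatinine: 88.42
unit_convert <- function(x, from, to) {
  factors <- c("g/dL->g/L" = 10,
               "g/L->g/dL" = 1 / 10,
               "mg/dL->umol/L" = 88.42,
               "umol/L->mg/dL" = 1 / 88.42,
               "mg/dL->mmol/L" = 1 / 18.016,
               "mmol/L->mg/dL" = 18.016)
  key <- paste0(from, "->", to)
  if (from == to) return(x)
  if (!key %in% names(factors)) {
    stop_config("unit_convert: unsupported conversion ", from, " -> ", to)
  }
  x * factors[[key]]
}
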