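#' Built-in biomarker panels
#'
#' Returns the biomarker column names of a named panel:
#' \describe{
#'   \item{`kdm8`}{creatinine, albumin, cholesterol, blood urea nitrogen,
#'     systolic and diastolic blood pressure, pulse, HbA1c — the eight
#'     markers screened in for the clinical-cohort analyses.}
#'   \item{`kdm7-accord`}{`kdm8` without blood urea nitrogen (it is absent
#'     from ACCORD-style trial records).}
#'   \item{`kdm8-crp`}{`kdm8` with C-reactive protein substituted for HbA1c
#'     (A1c is confounded by the diabetes diagnosis itself).}
#'   \item{`kdm7-nosbp`}{`kdm8` without systolic blood pressure.}
#'   \item{`phage9`}{the nine Levine phenotypic-age markers.}
#' }
#'
#' @param id Panel identifier.
#' @return Character vector of biomarker column names.
#' @export
#' @examples
#' bioage_panel("kdm7-accord")
bioage_panel <- function(id = c("kdm8", "kdm7-accord", "kdm8-crp",
                                "kdm7-nosbp", "phage9")) {
  id <- match.arg(id)
  kdm8 <- c("creatinine", "albumin", "cholesterol", "bun",
            "sbp", "dbp", "pulse", "a1c")
  switch(id,
    "kdm8" = kdm8,
    "kdm7-accord" = setdiff(kdm8, "bun"),
    "kdm8-crp" = c(setdiff(kdm8, "a1c"), "crp"),
    "kdm7-nosbp" = setdiff(kdm8, "sbp"),
    "phage9" = phage_marker_names())
}
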