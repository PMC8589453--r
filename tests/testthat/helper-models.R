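# Construct bioage model objects with known coefficients, bypassing fitting.

make_kdm_model <- function(q, k, s, panel = paste0("m", seq_along(q)),
                           gender = "female") {
  coefs <- data.frame(biomarker = panel, q = q, k = k, s = s)
  structure(list(method = "kdm1", panel = panel, genders = gender,
                 models = setNames(list(list(coefficients = coefs,
                                             n = NA_integer_)), gender),
                 ca_col = "ca", gender_col = "gender"),
            class = "bioage")
}

make_mlr_model <- function(b0, b, panel = paste0("m", seq_along(b)),
                           gender = "female") {
  cf <- c("(Intercept)" = b0, setNames(b, panel))
  structure(list(method = "mlr", panel = panel, genders = gender,
                 models = setNames(list(list(coefficients = cf,
                                             n = NA_integer_)), gender),
                 ca_col = "ca", gender_col = "gender"),
            class = "bioage")
}

subjects <- function(panel, values, gender = "female") {
  out <- as.data.frame(as.list(setNames(values, panel)))
  out$gender <- gender
  out$subject_id <- "s1"
  out
}
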