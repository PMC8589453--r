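test_that("KDM calibration recovers a noise-free generative law exactly", {
  specs <- list(biomarker_spec("m1", 10, 0.5, 0),
                biomarker_spec("m2", -3, -0.2, 0))
  co <- simulate_controls(cohort_config(n_subjects = 60, specs = specs,
                                        s_ba = 0, seed = 20))
  fit <- bioage(co, panel = c("m1", "m2"), method = "kdm1")
  cf <- coef(fit)
  expect_equal(cf$q[cf$biomarker == "m1"], rep(10, 2), tolerance = 1e-10)
  expect_equal(cf$k[cf$biomarker == "m1"], rep(0.5, 2), tolerance = 1e-10)
  expect_equal(cf$q[cf$biomarker == "m2"], rep(-3, 2), tolerance = 1e-10)
  expect_lt(max(cf$s), 1e-6)
  # and the whole loop returns BA = CA to machine precision
  pred <- predict(fit, co)
  expect_equal(pred$ba, co$ca, tolerance = 1e-8)
})

test_that("KDM calibration matches closed-form normal equations on a 3-point fixture", {
  tb <- data.frame(subject_id = c("a", "b", "c"), ca = c(30, 50, 70),
                   gender = "female", x = c(12, 19, 29))
  fit <- bioage(tb, panel = "x", method = "kdm1")
  cf <- coef(fit)
  # hand solution: slope = Sxy/Sxx, intercept = ybar - slope * xbar
  sl <- sum((tb$ca - 50) * (tb$x - 20)) / sum((tb$ca - 50)^2)
  ic <- 20 - sl * 50
  res <- tb$x - ic - sl * tb$ca
  expect_equal(cf$k, sl, tolerance = 1e-12)
  expect_equal(cf$q, ic, tolerance = 1e-12)
  expect_equal(cf$s, sqrt(sum(res^2) / 1), tolerance = 1e-12)
})

test_that("KDM fit recovers known parameters within sampling error", {
  co <- simulate_controls(cohort_config(n_subjects = 5000, seed = 21))
  fit <- bioage(co, method = "kdm1")
  cf <- coef(fit)
  specs <- kdm_panel_specs()
  for (m in names(specs)) {
    sp <- specs[[m]]
    rows <- cf[cf$biomarker == m, ]
    # total residual sd around CA combines marker noise and k * s_ba
    s_tot <- sqrt(sp$noise_sd^2 + (sp$slope * 5)^2)
    for (r in seq_len(nrow(rows))) {
      n <- fit$models[[rows$gender[r]]]$n
      se_k <- s_tot / (sd(co$ca) * sqrt(n))
      expect_lt(abs(rows$k[r] - sp$slope), 3.5 * se_k)
      expect_lt(abs(rows$s[r] - s_tot) / s_tot, 0.1)
    }
  }
})

test_that("KDM1 prediction inverts the biomarker laws", {
  # a subject lying exactly on a single biomarker law maps back to its CA
  m1 <- make_kdm_model(q = 10, k = 0.5, s = 2)
  expect_equal(predict(m1, subjects("m1", 10 + 0.5 * 47))$ba, 47)
  # two equally weighted biomarkers implying ages 40 and 60 average to 50
  m2 <- make_kdm_model(q = c(0, 0), k = c(1, 1), s = c(3, 3))
  expect_equal(predict(m2, subjects(c("m1", "m2"), c(40, 60)))$ba, 50)
  # hand-evaluated weighted-sum fixture
  m3 <- make_kdm_model(q = c(10, 5), k = c(0.5, -0.2), s = c(1, 2))
  expect_equal(predict(m3, subjects(c("m1", "m2"), c(35, -6)))$ba,
               13.05 / 0.26, tolerance = 1e-12)
})

test_that("KDM1 equals the weighted-least-squares minimiser on random instances", {
  set.seed(22)
  for (i in 1:100) {
    p <- sample(2:6, 1)
    q <- rnorm(p, 0, 20)
    k <- rnorm(p, 0, 1)
    k[abs(k) < 0.05] <- 0.3
    s <- runif(p, 0.5, 4)
    x <- q + k * runif(1, 20, 80) + rnorm(p, 0, s)
    mod <- make_kdm_model(q, k, s)
    expect_equal(predict(mod, subjects(paste0("m", 1:p), x))$ba,
                 kdm_wls_oracle(x, q, k, s), tolerance = 1e-8)
  }
})

test_that("KDM1 is invariant to rescaling a biomarker with its triple", {
  set.seed(23)
  q <- c(5, -2, 8); k <- c(0.4, -0.3, 0.6); s <- c(1, 2, 1.5)
  x <- c(25, -17, 40)
  base <- predict(make_kdm_model(q, k, s), subjects(paste0("m", 1:3), x))$ba
  fac <- 37.5
  q2 <- q; k2 <- k; s2 <- s; x2 <- x
  q2[2] <- q[2] * fac; k2[2] <- k[2] * fac; s2[2] <- s[2] * fac
  x2[2] <- x[2] * fac
  rescaled <- predict(make_kdm_model(q2, k2, s2),
                      subjects(paste0("m", 1:3), x2))$ba
  expect_equal(base, rescaled, tolerance = 1e-10)
})

test_that("prediction rejects unknown genders and missing biomarkers", {
  mod <- make_kdm_model(10, 0.5, 2, gender = "female")
  sub <- subjects("m1", 30, gender = "male")
  expect_error(predict(mod, sub), "male", class = "clinage_config_error")
  expect_error(predict(mod, data.frame(gender = "female")),
               class = "clinage_schema_error")
  co <- simulate_controls(cohort_config(n_subjects = 50, seed = 1,
                                        missing_rate = 0.2))
  co <- co[co$gender == "female", , drop = FALSE]
  fit <- make_kdm_model(10, 0.5, 2, panel = "sbp")
  expect_error(predict(fit, co), "missing", class = "clinage_config_error")
})

test_that("constant biomarkers abort the KDM fit by name", {
  tb <- data.frame(subject_id = letters[1:20], ca = 21:40,
                   gender = "female", flat = 7, ok = 21:40 + rnorm(20))
  expect_error(bioage(tb, panel = c("flat", "ok"), method = "kdm1"),
               "flat", class = "clinage_config_error")
})

test_that("MLR reduces to the identity on a noise-free single marker", {
  tb <- data.frame(subject_id = sprintf("s%02d", 1:30),
                   ca = seq(20, 78, by = 2), gender = "male")
  tb$x <- tb$ca
  fit <- bioage(tb, panel = "x", method = "mlr")
  b <- coef(fit)
  expect_equal(unname(b[1, 1]), 0, tolerance = 1e-10)
  expect_equal(unname(b[1, 2]), 1, tolerance = 1e-10)
  expect_equal(predict(fit, tb)$ba, tb$ca, tolerance = 1e-10)
})

test_that("MLR coefficients match the normal-equations oracle on a small fixture", {
  tb <- data.frame(subject_id = letters[1:4], ca = c(30, 45, 55, 70),
                   gender = "female",
                   x1 = c(1.0, 2.0, 2.5, 4.0), x2 = c(10, 8, 7, 3))
  fit <- bioage(tb, panel = c("x1", "x2"), method = "mlr")
  oracle <- normal_equations_oracle(as.matrix(tb[, c("x1", "x2")]), tb$ca)
  expect_equal(unname(coef(fit)[1, ]), unname(oracle), tolerance = 1e-8)
})

test_that("MLR prediction is the stored linear form", {
  mod0 <- make_mlr_model(b0 = 33, b = c(0, 0))
  expect_equal(predict(mod0, subjects(c("m1", "m2"), c(5, -2)))$ba, 33)
  mod <- make_mlr_model(b0 = 20, b = c(2, -1))
  expect_equal(predict(mod, subjects(c("m1", "m2"), c(15, 5)))$ba, 45)
})

test_that("MLR regresses toward the mean when biomarkers are uninformative", {
  set.seed(24)
  n <- 800
  tb <- data.frame(subject_id = sprintf("s%04d", 1:n),
                   ca = runif(n, 20, 80),
                   gender = rep(c("male", "female"), n / 2),
                   x1 = rnorm(n), x2 = rnorm(n))
  sp <- train_test_split(tb, 0.5, seed = 1)
  fit <- bioage(sp$train, panel = c("x1", "x2"), method = "mlr")
  pred <- predict(fit, sp$test)
  slope <- coef(lm(pred$ba ~ sp$test$ca))[2]
  expect_lt(abs(slope), 0.15)
  # predictions collapse toward the mean training age
  expect_lt(sd(pred$ba), 0.2 * sd(sp$test$ca))
})

test_that("rank-deficient MLR designs fail with the collinear columns listed", {
  tb <- data.frame(subject_id = letters[1:10], ca = 31:40, gender = "male",
                   x1 = 1:10, x2 = 2 * (1:10))
  expect_error(bioage(tb, panel = c("x1", "x2"), method = "mlr"),
               "x2", class = "clinage_config_error")
})

test_that("unit conversions are exact and invertible", {
  expect_equal(unit_convert(4.0, "g/dL", "g/L"), 40)
  expect_equal(unit_convert(1.0, "mg/dL", "umol/L"), 88.42)
  glu <- unit_convert(unit_convert(100, "mg/dL", "mmol/L"), "mmol/L", "mg/dL")
  expect_equal(glu, 100, tolerance = 1e-12)
  expect_error(unit_convert(1, "mg/dL", "furlongs"),
               class = "clinage_config_error")
})
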