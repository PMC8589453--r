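test_that("box_cox matches its closed forms at fixed lambda", {
  x <- c(1, 2, 3, 4, 5, 10)
  expect_equal(box_cox(x, lambda = 1)$values, x - 1)
  expect_equal(box_cox(x, lambda = 0)$values, log(x))
  expect_error(box_cox(c(1, -2, 3), lambda = 0.5), class = "clinage_domain_error")
})

test_that("estimated lambda equals the grid-search argmax of the profile likelihood", {
  x <- rep(c(1, 2, 3, 4, 5, 10), 2)
  fit <- box_cox(x)
  grid <- seq(-5, 5, by = 0.001)
  ll <- vapply(grid, function(l) clinage:::boxcox_loglik(x, l), 1)
  expect_lt(abs(fit$lambda - grid[which.max(ll)]), 2e-3)
  # and on a skewed sample the transform should pull lambda below 1
  set.seed(12)
  y <- exp(rnorm(200, 1, 0.4))
  fit2 <- box_cox(y)
  expect_lt(fit2$lambda, 0.6)
  grid_max <- grid[which.max(vapply(grid, function(l) clinage:::boxcox_loglik(y, l), 1))]
  expect_lt(abs(fit2$lambda - grid_max), 2e-3)
  # cross-check against an established profile-likelihood implementation
  bc <- MASS::boxcox(y ~ 1, lambda = seq(-2, 2, by = 0.001), plotit = FALSE)
  expect_lt(abs(fit2$lambda - bc$x[which.max(bc$y)]), 2e-3)
})

test_that("transform is skipped for vectors with non-positive values", {
  expect_equal(box_cox_decision(c(70, 80, 0, 75)), "skip")
  expect_equal(box_cox_decision(c(70, 80, 75)), "transform")
  expect_equal(box_cox_decision(c(-3, -1)), "skip")
})

test_that("winsorize shrinks only the tails and is idempotent", {
  x <- c(5, 6, 7, 8)
  expect_equal(winsorize(x, c(0.01, 0.99)), x)  # interior untouched
  expect_equal(winsorize(rep(3, 10)), rep(3, 10))

  y <- c(1:99, 1000)
  w <- winsorize(y, c(0.01, 0.99))
  expect_equal(max(w), sort(y)[99])  # sort-based oracle for the 99th percentile
  expect_equal(w[1:99], y[1:99])

  set.seed(21)
  for (i in 1:20) {
    z <- rnorm(57)
    once <- winsorize(z, c(0.05, 0.95))
    expect_equal(winsorize(once, c(0.05, 0.95)), once)
  }
  expect_error(winsorize(y, c(0.9, 0.1)), class = "clinage_config_error")
})

test_that("gender adjustment equalises gender means exactly", {
  g <- rep(c("male", "female"), each = 6)
  x <- c(rep(10, 6), rep(20, 6))
  expect_equal(gender_adjust(x, g), rep(15, 12))

  set.seed(5)
  v <- rnorm(50)
  gg <- rep(c("male", "female"), 25)
  expect_lt(max(abs(gender_adjust(v, gg) - v)), 1)  # nearly unchanged
  expect_lt(abs(mean(gender_adjust(v, gg)) - mean(v)), 1e-12)

  # known gap of 4 years, unbalanced groups, against the two-group closed form
  gu <- c(rep("male", 30), rep("female", 20))
  base <- rnorm(50)
  xv <- base + ifelse(gu == "male", 4, 0)
  adj <- gender_adjust(xv, gu)
  expect_lt(abs(mean(adj[gu == "male"]) - mean(adj[gu == "female"])), 1e-9)
  oracle <- xv - ifelse(gu == "male",
                        mean(xv[gu == "male"]), mean(xv[gu == "female"])) +
    mean(xv)
  expect_equal(adj, oracle, tolerance = 1e-9)
  expect_error(gender_adjust(xv, rep("male", 50)), class = "clinage_config_error")
})

test_that("univariate screening detects signal and controls type-I error", {
  n <- 200
  set.seed(8)
  tb <- data.frame(ca = runif(n, 20, 80))
  tb$perfect <- 2 * tb$ca
  tb$flat <- rep(1, n)
  rep1 <- suppressWarnings(univariate_screen(tb, c("perfect", "flat")))
  expect_s3_class(rep1, "screen_report")
  expect_true(rep1$selected[rep1$biomarker == "perfect"])
  expect_equal(rep1$r_squared[rep1$biomarker == "perfect"], 1, tolerance = 1e-12)
  expect_false(rep1$selected[rep1$biomarker == "flat"])

  # permuted CA is selected in about 5% of replicates at threshold 0.05
  set.seed(9)
  n0 <- 40
  ca0 <- runif(n0, 20, 80)
  hits <- logical(1000)
  for (i in seq_len(1000)) {
    d <- data.frame(ca = ca0, null = sample(ca0))
    hits[i] <- univariate_screen(d, "null")$selected
  }
  expect_gt(mean(hits), 0.025)
  expect_lt(mean(hits), 0.075)
})

test_that("redundancy flags use a strict cutoff on |r|", {
  set.seed(10)
  tb <- data.frame(a = rnorm(1000))
  tb$b <- tb$a  # duplicate
  tb$c <- rnorm(1000)
  flagged <- redundancy_check(tb, c("a", "b", "c"))
  expect_equal(nrow(flagged), 1)
  expect_equal(abs(flagged$correlation), 1, tolerance = 1e-12)

  # independent noise never trips the 0.75 cutoff at n = 1000
  set.seed(11)
  for (i in 1:100) {
    d <- data.frame(x = rnorm(1000), y = rnorm(1000))
    expect_equal(nrow(redundancy_check(d, c("x", "y"))), 0)
  }

  # a pair exactly at the cutoff is not flagged (strict inequality)
  r_exact <- abs(cor(tb$a, tb$c))
  expect_equal(nrow(redundancy_check(tb, c("a", "c"), r_cutoff = r_exact)), 0)
})

test_that("the CA-paradox flag is advisory and strict", {
  expect_true(ca_paradox_flag(0.36))
  expect_false(ca_paradox_flag(0.26))
  expect_false(ca_paradox_flag(0.32))
  expect_error(ca_paradox_flag(1.2), class = "clinage_domain_error")
  # flagged markers are retained by the screen, only marked
  set.seed(13)
  tb <- data.frame(ca = runif(500, 20, 80))
  tb$tight <- 0.5 * tb$ca + rnorm(500, 0, 2)
  rep2 <- univariate_screen(tb, "tight")
  expect_true(rep2$selected[1])
  expect_true(rep2$ca_paradox[1])
})

test_that("standardisation in the fitted recipe gives mean 0, sd 1 on training data", {
  co <- simulate_controls(cohort_config(n_subjects = 400, seed = 14))
  panel <- bioage_panel("kdm8")
  spec <- fit_transform_spec(co, panel, winsor_limits = c(0, 1),
                             use_gender_adjust = FALSE)
  out <- apply_transform_spec(spec, co)
  for (m in panel) {
    expect_lt(abs(mean(out[[m]])), 1e-12)
    expect_lt(abs(sd(out[[m]]) - 1), 1e-12)
  }
})

test_that("the fitted recipe is frozen: new data reuse training parameters", {
  co <- simulate_controls(cohort_config(n_subjects = 400, seed = 15))
  panel <- c("sbp", "a1c")
  spec <- fit_transform_spec(co, panel)
  shifted <- co
  shifted$sbp <- shifted$sbp + 50
  out <- apply_transform_spec(spec, shifted)
  # a +50 mmHg shift must survive as a large positive standardised mean
  # (capped by the frozen winsor bounds), which could not happen if the
  # recipe were refit on the new data
  expect_gt(mean(out$sbp), 1.5)
})

test_that("screening on an adequately sized synthetic panel selects every true signal", {
  co <- simulate_controls(cohort_config(n_subjects = 1500, seed = 16))
  panel <- bioage_panel("kdm8")
  spec <- fit_transform_spec(co, panel)
  rep3 <- univariate_screen(apply_transform_spec(spec, co), panel)
  expect_true(all(rep3$selected))
})
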