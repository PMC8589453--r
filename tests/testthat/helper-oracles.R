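# Independent oracles used by the tests. These deliberately avoid the
# package's own code paths.

# Weighted-least-squares oracle for the KDM1 point estimate: minimise
# sum_j ((x_j - q_j - k_j * ba) / s_j)^2 over ba by 1-D numeric search.
kdm_wls_oracle <- function(x, q, k, s) {
  obj <- function(ba) sum(((x - q - k * ba) / s)^2)
  stats::optimize(obj, interval = c(-500, 1000), tol = 1e-10)$minimum
}

# Normal-equations oracle for OLS coefficients of y on X (with intercept).
normal_equations_oracle <- function(X, y) {
  A <- cbind(1, X)
  solve(t(A) %*% A, t(A) %*% y)[, 1]
}

# Log partial likelihood for a Cox model with one covariate and untied
# event times, by explicit risk-set enumeration.
cox_loglik_oracle <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- which(time >= time[i])
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

cox_beta_oracle <- function(time, event, x) {
  stats::optimize(function(b) cox_loglik_oracle(b, time, event, x),
                  interval = c(-10, 10), maximum = TRUE, tol = 1e-10)$maximum
}

# Term-by-term phenotypic-age calculator (additive signed reading),
# written out longhand and independent of phage_spec().
phage_calculator_oracle <- function(albumin, creatinine, glucose, crp,
                                    lymphocyte_pct, mcv, rdw, alp, wbc, ca) {
  t1 <- -19.907
  t2 <- -0.0336 * albumin
  t3 <- 0.0095 * creatinine
  t4 <- 0.0195 * glucose
  t5 <- 0.0954 * log(crp)
  t6 <- -0.0120 * lymphocyte_pct
  t7 <- 0.0268 * mcv
  t8 <- 0.3356 * rdw
  t9 <- 0.00188 * alp
  t10 <- 0.0554 * wbc
  t11 <- 0.0804 * ca
  xb <- t1 + t2 + t3 + t4 + t5 + t6 + t7 + t8 + t9 + t10 + t11
  141.50 + log(-0.0053 * log(1 - xb)) / 0.09165
}

# Brute-force minimum-total-age-distance assignment of cases to distinct
# same-gender controls (for small fixtures).
matching_oracle <- function(cases, controls, caliper) {
  best <- NULL
  best_cost <- Inf
  n_cases <- nrow(cases)
  recurse <- function(i, used, pairs, cost) {
    if (i > n_cases) {
      # maximise pair count first, then minimise cost
      if (is.null(best) || nrow(pairs) > nrow(best) ||
          (nrow(pairs) == nrow(best) && cost < best_cost)) {
        best <<- pairs
        best_cost <<- cost
      }
      return(invisible())
    }
    elig <- which(!used & controls$gender == cases$gender[i] &
                    abs(controls$ca - cases$ca[i]) <= caliper)
    for (j in elig) {
      used[j] <- TRUE
      recurse(i + 1, used,
              rbind(pairs, data.frame(case_id = cases$subject_id[i],
                                      control_id = controls$subject_id[j])),
              cost + abs(controls$ca[j] - cases$ca[i]))
      used[j] <- FALSE
    }
    recurse(i + 1, used, pairs, cost)  # leave case i unmatched
  }
  recurse(1, rep(FALSE, nrow(controls)),
          data.frame(case_id = character(), control_id = character()), 0)
  list(pairs = best, cost = best_cost)
}
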