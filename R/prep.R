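#' Apply inclusion/exclusion rules to a cohort table
#'
#' Applies, in order: (1) removal of control rows whose HbA1c is at or above
#' the prediabetes cutoff (the cutoff is strict: controls must have A1c
#' strictly below it, so undiagnosed prediabetes is excluded), (2) removal
#' of rows with a missing value in any required column, and (3) removal of
#' rows outside the age bounds. The rules are conjunctive filters, so the
#' surviving membership does not depend on their order; the attached log
#' records how many rows each rule removed in application order.
#'
#' @param data Cohort data frame with `ca`, `gender` and `group` columns.
#' @param a1c_cutoff Prediabetes threshold in percent (default 5.7).
#' @param age_bounds Inclusive age bounds in years (default 20-80).
#' @param required Columns that must be non-missing; defaults to `ca`,
#'   `gender` and any `a1c` column present.
#' @param a1c_col Name of the HbA1c column; the cutoff rule is skipped with
#'   a warning when absent and no control filtering was requested.
#' @return The filtered data frame with attribute `"exclusion_log"`, a data
#'   frame of `rule` and `n_removed`.
#' @export
#' @examples
#' cfg <- cohort_config(n_subjects = 50, seed = 1)
#' kept <- apply_exclusions(simulate_controls(cfg))
#' attr(kept, "exclusion_log")
apply_exclusions <- function(data, a1c_cutoff = 5.7, age_bounds = c(20, 80),
                             required = NULL, a1c_col = "a1c") {
  check_columns(data, c("ca", "gender", "group"), "apply_exclusions")
  if (is.null(required)) {
    required <- intersect(c("ca", "gender", a1c_col), names(data))
  } else {
    check_columns(data, required, "apply_exclusions: required columns")
  }
  log <- data.frame(rule = character(), n_removed = integer())
  note <- function(rule, n) rbind(log, data.frame(rule = rule, n_removed = n))

  if (a1c_col %in% names(data)) {
    bad <- data$group == "control" & !is.na(data[[a1c_col]]) &
      data[[a1c_col]] >= a1c_cutoff
    log <- note(sprintf("control %s >= %g", a1c_col, a1c_cutoff), sum(bad))
    data <- data[!bad, , drop = FALSE]
  }

  has_na <- rowSums(is.na(data[, required, drop = FALSE])) > 0
  log <- note("missing required value", sum(has_na))
  data <- data[!has_na, , drop = FALSE]

  out_of_age <- is.na(data$ca) | data$ca < age_bounds[1] | data$ca > age_bounds[2]
  log <- note(sprintf("age outside [%g, %g]", age_bounds[1], age_bounds[2]),
              sum(out_of_age))
  data <- data[!out_of_age, , drop = FALSE]

  rownames(data) <- NULL
  attr(data, "exclusion_log") <- log
  data
}

#' Match cases to controls on age within gender
#'
#' Greedy nearest-age matching without replacement: cases are processed in
#' input order and each takes the unused same-gender control closest in age,
#' provided the age difference is within the caliper. Ties in age distance
#' are broken by a seeded random draw. Cases with no eligible control are
#' reported, not fatal.
#'
#' @param cases,controls Data frames with `subject_id`, `ca` and `gender`.
#' @param caliper Maximum absolute age difference in years (default 2).
#' @param seed Integer seed for tie-breaking; `NULL` uses the current stream.
#' @return An object of class `"match_result"`: list with `pairs` (data
#'   frame of `case_id`, `control_id`, `age_diff`), `unmatched_cases`, and
#'   `caliper`.
#' @export
match_case_control <- function(cases, controls, caliper = 2, seed = NULL) {
  for (tb in list(cases, controls)) {
    check_columns(tb, c("subject_id", "ca", "gender"), "match_case_control")
  }
  if (nrow(cases) == 0L || nrow(controls) == 0L) {
    stop_config("match_case_control: `cases` and `controls` must be non-empty")
  }
  with_seed(seed, {
    used <- rep(FALSE, nrow(controls))
    pairs <- vector("list", nrow(cases))
    unmatched <- character()
    for (i in seq_len(nrow(cases))) {
      ok <- !used & controls$gender == cases$gender[i]
      d <- abs(controls$ca - cases$ca[i])
      ok <- ok & d <= caliper
      if (!any(ok)) {
        unmatched <- c(unmatched, cases$subject_id[i])
        next
      }
      dmin <- min(d[ok])
      cand <- which(ok & d <= dmin + 1e-12)
      j <- if (length(cand) > 1L) cand[sample.int(length(cand), 1L)] else cand
      used[j] <- TRUE
      pairs[[i]] <- data.frame(case_id = cases$subject_id[i],
                               control_id = controls$subject_id[j],
                               age_diff = d[j])
    }
    pairs <- do.call(rbind, pairs[!vapply(pairs, is.null, TRUE)])
    if (is.null(pairs)) {
      pairs <- data.frame(case_id = character(), control_id = character(),
                          age_diff = numeric())
    }
    structure(list(pairs = pairs, unmatched_cases = unmatched,
                   caliper = caliper),
              class = "match_result")
  })
}

#' @export
print.match_result <- function(x, ...) {
  cat("Case-control matching (caliper ", x$caliper, " y): ",
      nrow(x$pairs), " pairs, ", length(x$unmatched_cases),
      " unmatched case(s)\n", sep = "")
  invisible(x)
}

#' Split controls into training and held-out sets, stratified by gender
#'
#' Per gender stratum, `round(n * train_fraction)` subjects are sampled
#' without replacement into the training set so that both per-gender models
#' remain trainable; the remainder form the held-out set. The default
#' fraction of two thirds mirrors the conventional calibration split.
#'
#' @param data Control data frame with a `gender` column.
#' @param train_fraction Proportion in (0, 1); default `2/3`.
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @return List with elements `train` and `test`, disjoint and exhaustive.
#' @export
train_test_split <- function(data, train_fraction = 2 / 3, seed = NULL) {
  check_columns(data, "gender", "train_test_split")
  if (!is.numeric(train_fraction) || train_fraction <= 0 || train_fraction >= 1) {
    stop_config("train_test_split: `train_fraction` must be in (0, 1)")
  }
  strata <- split(seq_len(nrow(data)), data$gender)
  small <- names(strata)[vapply(strata, length, 1L) < 2L]
  if (length(small)) {
    stop_config("train_test_split: gender stratum with < 2 rows: ",
                paste(small, collapse = ", "))
  }
  with_seed(seed, {
    train_idx <- unlist(lapply(strata, function(idx) {
      k <- round(length(idx) * train_fraction)
      k <- max(1L, min(length(idx) - 1L, k))  # keep both sides non-empty
      sample(idx, k)
    }), use.names = FALSE)
    list(train = data[sort(train_idx), , drop = FALSE],
         test = data[setdiff(seq_len(nrow(data)), train_idx), , drop = FALSE])
  })
}
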