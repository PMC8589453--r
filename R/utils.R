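# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards so simulation calls do not perturb each other.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("clinage_config_error", "error")))
}

stop_schema <- function(...) {
  stop(errorCondition(paste0(...), class = c("clinage_schema_error", "error")))
}

stop_domain <- function(...) {
  stop(errorCondition(paste0(...), class = c("clinage_domain_error", "error")))
}

check_columns <- function(data, cols, where) {
  missing <- setdiff(cols, names(data))
  if (length(missing)) {
    stop_schema(where, ": missing column(s) ", paste(missing, collapse = ", "))
  }
  invisible(TRUE)
}
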