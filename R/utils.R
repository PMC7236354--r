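#' @noRd
stop_bad_arg <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "icatest_invalid_argument")
}

#' @noRd
assert_that <- function(ok, msg, ...) {
  if (!isTRUE(ok)) stop_bad_arg(msg, ...)
  invisible(TRUE)
}

# Run code under a local RNG state seeded by `seed`, restoring the caller's
# stream afterwards so library calls never perturb user-level reproducibility.
#' @noRd
with_seed <- function(seed, code) {
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

# OLS slope of y on x in closed form; NA-safe length checks are the caller's.
#' @noRd
ols_slope <- function(x, y) {
  vx <- sum((x - mean(x))^2)
  if (vx == 0) return(NA_real_)
  sum((x - mean(x)) * (y - mean(y))) / vx
}
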