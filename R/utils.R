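# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG state
#'
#' Runs `expr` with the global RNG seeded to `seed`, then restores the caller's
#' RNG state, so seeded routines do not perturb the user's random stream.
#'
#' @param seed integer seed
#' @param expr expression to evaluate
#' @return the value of `expr`
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
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
  expr
}

# Derive a child seed from a parent seed and small stream indices; stays well
# below 2^31 so the result is always a valid R integer seed.
derive_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed) %% 1000003
  for (i in idx) {
    s <- (s * 131 + as.double(i) + 7) %% 1000003
  }
  as.integer(s + 1)
}

stop_bisguard <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "bisguard_error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
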