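#' Run code under a temporary RNG seed
#'
#' Evaluates `expr` with the global RNG seeded to `seed`, then restores the
#' previous RNG state, so package functions never leak RNG state into the
#' caller's session. All stochastic operations in the package draw their
#' randomness through this helper.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
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

#' Derive a stream seed from a base seed
#'
#' Deterministic splitting scheme: every stochastic stage of the workflow uses
#' `derive_seed(seed, stream)` with a fixed per-stage stream id, so a single
#' user-facing seed governs the whole run while stages remain independent.
#' The result is kept inside the positive 32-bit integer range.
#'
#' @param seed integer base seed.
#' @param stream small non-negative integer identifying the consumer.
#' @return integer seed.
#' @export
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  stopifnot(is.numeric(stream), length(stream) == 1, stream >= 0)
  as.integer((abs(as.numeric(seed)) * 1009 + as.numeric(stream) * 9973 + 1) %%
               2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}
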