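#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the random seed, evaluates `code`, and restores the previous RNG
#' state, so seeded generator calls do not disturb the caller's random
#' stream.  All randomness in the synthetic-data module flows through this
#' helper from a single explicit seed.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop_reec("'seed' must be a single finite number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a deterministic sub-seed
#'
#' Maps a master seed and an operation index to a sub-seed below 2^31, so
#' that multi-step generators (e.g. a disk time series) draw independent but
#' reproducible streams from one user-facing seed.
#'
#' @param seed Master integer seed.
#' @param offset Non-negative integer identifying the consuming operation.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, offset = 0L) {
  s <- (as.double(seed) %% 2147483647) * 48271 + as.double(offset) * 10007 + 1
  as.integer(s %% 2147483647)
}
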