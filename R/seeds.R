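# RNG plumbing shared by all stochastic operations.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves the current state of R's random number generator, seeds it with
#' `seed`, evaluates `expr`, and restores the previous state afterwards, so
#' that seeded operations are pure functions of their arguments and do not
#' disturb the caller's RNG stream.  A `NULL` seed evaluates `expr` with the
#' ambient stream.
#'
#' @param seed Integer seed or `NULL`.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a reproducible child seed from a master seed
#'
#' Deterministic, platform-independent splitting of a master seed into
#' per-replicate child seeds via a 32-bit linear congruential mix.  The result
#' always lies in `[1, 2^31 - 2]` so it is a valid argument to [set.seed()].
#'
#' @param master Integer master seed.
#' @param k Non-negative integer index of the child stream.
#' @return An integer seed.
#' @export
#' @examples
#' derive_seed(42, 1)
#' derive_seed(42, 2)
derive_seed <- function(master, k) {
  m <- 2147483647 # 2^31 - 1 (prime)
  x <- (as.double(master) %% m)
  for (i in seq_len(k + 1L)) {
    x <- (48271 * x + 12345 + 7919 * k) %% m
  }
  as.integer(max(1, x %% (m - 1)))
}
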