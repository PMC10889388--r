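# Local RNG handling: every stochastic operation takes an integer seed and
# runs under with_seed(), which saves and restores the caller's RNG state, so
# no function mutates global randomness. Sub-streams are derived from the
# parent seed with derive_seed(), a deterministic counter-based split.

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the RNG to a reproducible state, evaluates `expr`, then restores the
#' caller's RNG state, so package functions never perturb global randomness.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    # materialize a state to save
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' Derive a child seed from a parent seed and a counter
#'
#' Deterministic counter-based seed splitting: independent sub-streams
#' (per scene, per seed, per fold) are keyed by `(seed, counter)` so that the
#' whole pipeline is reproducible from one integer.
#'
#' @param seed Parent integer seed.
#' @param counter Non-negative integer stream index.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @keywords internal
derive_seed <- function(seed, counter) {
  # affine mixing mod the Mersenne prime 2^31 - 1; multipliers are fixed
  # odd constants, nothing is tuned
  m <- 2147483647
  s <- (as.numeric(seed) %% m) * 48271 %% m
  s <- (s + (as.numeric(counter) + 1) * 69621) %% m
  as.integer(s %% (m - 1) + 1)
}
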