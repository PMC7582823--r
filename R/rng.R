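#' Run code with a temporary RNG seed
#'
#' Evaluates `code` with the global random number generator seeded to `seed`,
#' then restores the previous generator state, so package functions never leak
#' randomness into (or depend on) the caller's session state.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

# Deterministically derive a sub-stream seed from (seed, index). Constants are
# arbitrary primes; products stay < 2^53 so double arithmetic is exact, and the
# result stays < 2^31 (R integer range).
derive_seed <- function(seed, index) {
  s <- (as.numeric(seed) %% 69999989) * 30011 + as.numeric(index) * 7919 + 104729
  as.integer(s %% 2147483587)
}
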