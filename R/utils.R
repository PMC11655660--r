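#' Derive a child seed from a master seed
#'
#' All stochastic stages of the package draw their seeds from one master
#' seed through this deterministic mixing scheme, so that a full run is
#' reproducible from a single integer while independent stages (subjects,
#' repetitions, permutations) still receive distinct streams.
#'
#' The scheme is a multiplicative-congruential fold: starting from the
#' master seed, each tag `k` updates the state as
#' `s <- (s * 69069 + k + 1) mod (2^31 - 1)`. The multiplier keeps all
#' intermediate products below 2^53 so the arithmetic is exact in doubles.
#'
#' @param seed master seed (integer).
#' @param ... integer tags identifying the stage (e.g. subject index,
#'   repetition index). Order matters.
#' @return an integer seed in `[1, 2^31 - 1]`.
#' @export
derive_seed <- function(seed, ...) {
  tags <- c(...)
  s <- as.numeric(seed) %% 2147483647
  for (k in tags) {
    s <- (s * 69069 + as.numeric(k) + 1) %% 2147483647
  }
  as.integer(s %% 2147483646) + 1L
}

# Evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

# Symmetric Hann taper of length n.
hann_window <- function(n) {
  if (n == 1) return(1)
  0.5 * (1 - cos(2 * pi * seq(0, n - 1) / (n - 1)))
}
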