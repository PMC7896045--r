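#' Derive a reproducible child seed
#'
#' All randomness in the package flows from a single integer seed; component
#' seeds are derived deterministically from it and a string tag so that
#' subsystems (corpus generation, weight init, batch sampling, bootstraps)
#' never share or reuse RNG streams.
#'
#' @param seed integer master seed.
#' @param tag character tag naming the consumer.
#' @return an integer in [1, 2^31 - 2].
#' @export
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  h <- 0
  for (ch in utf8ToInt(tag)) h <- (h * 31 + ch) %% 2147483647
  as.integer((abs(seed) %% 2147483647 * 48271 + h) %% 2147483646 + 1)
}

# Run code under a seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a
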