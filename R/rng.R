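#' Derive a child seed from a master seed and a stream label
#'
#' All stochastic operations in the package take an integer seed. Composite
#' operations (experiment generation, cross-validation, the empirical
#' pipeline) derive one child seed per internal random stream from their own
#' seed and a fixed label, so that every experiment is bit-reproducible from a
#' single master seed and streams never collide across stages.
#'
#' The derivation is a 31-bit multiplicative hash: the label is folded into an
#' integer h by Horner's rule over its byte values (base 31, modulo 2^31-1),
#' then combined with the seed as (seed * 48271 + h) mod (2^31 - 1), plus one
#' to keep the result strictly positive. R integers are 32-bit, so all
#' arithmetic is done in double precision (exact below 2^53).
#'
#' @param seed Integer master seed.
#' @param label Character scalar naming the stream.
#' @return A positive integer seed, strictly below 2^31.
#' @examples
#' childSeed(42L, "training")
#' childSeed(42L, "test")
#' @export
childSeed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.character(label), length(label) == 1L)
  M <- 2147483647
  h <- 0
  for (b in utf8ToInt(label)) h <- (h * 31 + b) %% M
  as.integer(((abs(seed) %% M) * 48271 + h) %% M + 1)
}
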