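#' Derive a sub-stream seed from a root seed
#'
#' Every stochastic operation in the package takes an explicit seed. When a
#' single root seed governs several independent random streams (e.g. the
#' Hi-C simulator and the control simulator in one run), per-stream seeds
#' are derived deterministically so that streams do not collide and results
#' are reproducible from the root seed alone.
#'
#' The derivation is a fixed affine map modulo the Mersenne prime
#' 2^31 - 1, computed in double precision (exact for these magnitudes), so
#' derived seeds always fit a 32-bit R integer.
#'
#' @param seed integer root seed.
#' @param stream small non-negative integer (or character label, hashed to
#'   one) identifying the stream.
#' @return an integer seed in \[1, 2^31 - 2\].
#' @examples
#' derive_seed(1L, 0)
#' derive_seed(1L, "control")
#' @export
derive_seed <- function(seed, stream = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (is.character(stream)) {
    stream <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  }
  m <- 2147483647 # 2^31 - 1
  s <- (abs(seed) %% m)
  # two rounds of multiply-add keep distinct (seed, stream) pairs distinct
  # in practice without needing 64-bit integers
  s <- (s * 48271 + stream * 1009 + 1) %% m
  s <- (s * 16807 + 12345) %% m
  as.integer(s + (s == 0))
}

with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}
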