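#' Round half away from zero
#'
#' Rounds to the nearest integer with ties going away from zero (so 64.5
#' becomes 65 and -64.5 becomes -65), unlike base [round()] which rounds
#' half to even. This is the tie policy used when averaging daily THI over
#' the test-day window.
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @export
#' @examples
#' roundHalfAwayFromZero(c(64.5, 63.4, -0.5))
roundHalfAwayFromZero <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# Deterministic child seed from a master seed; keeps results < 2^31.
childSeed <- function(master, k) {
  as.integer((as.numeric(master) * 7919 + 1000003 * k) %% 2147483587L)
}

gaussBand <- function(center, width, height = 1, n = 1060L) {
  height * exp(-((seq_len(n) - center) / width)^2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
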