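#' Wrap a phase to the half-open interval (-0.5, 0.5] cycles
#'
#' Phases (interaural phase differences, characteristic phases, circular
#' residuals) are expressed in cycles throughout the package; this is the
#' canonical representative of a phase on the circle.
#'
#' @param x numeric vector of phases in cycles.
#' @return numeric vector wrapped to (-0.5, 0.5].
#' @export
#' @examples
#' wrapPhase(c(0.75, -0.5, 0.5, 1.2))
wrapPhase <- function(x) {
  x - ceiling(x - 0.5)
}

#' Circular mean of phases in cycles
#'
#' @param x phases in cycles.
#' @return circular mean in (-0.5, 0.5]; NA if the resultant length is
#'   numerically zero (mean direction undefined).
#' @export
circMeanCycles <- function(x) {
  z <- mean(exp(2i * pi * x))
  if (Mod(z) < 1e-12) return(NA_real_)
  wrapPhase(Arg(z) / (2 * pi))
}

#' Circular distance between phases, in cycles
#'
#' Shortest signed distance on the circle, in (-0.5, 0.5].
#'
#' @param a,b phases in cycles.
#' @return signed circular difference a - b.
#' @export
circDiffCycles <- function(a, b) {
  wrapPhase(a - b)
}

#' Circular root-mean-square deviation in cycles
#'
#' @param a,b phase vectors in cycles.
#' @return scalar RMS of the shortest circular differences.
#' @export
circRmsCycles <- function(a, b) {
  d <- circDiffCycles(a, b)
  sqrt(mean(d^2))
}

# mean resultant length of a set of phases (cycles); in [0, 1]
resultantLength <- function(x) {
  Mod(mean(exp(2i * pi * x)))
}
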