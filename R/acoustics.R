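#' Head geometry for interaural time differences
#'
#' The interaural angle \eqn{\theta} (azimuth on the zero-elevation great
#' circle, in radians, positive contralateral) maps to an ITD through the
#' spherical-head path-difference (Blauert) formula
#' \deqn{\tau(\theta) = \frac{d}{2c}(\theta + \sin\theta),}
#' with inter-ear distance \eqn{d} and sound speed \eqn{c}. The maximal
#' (fully lateral) ITD \eqn{\tau_{max} = \tau(\pi/2)} bounds the
#' physiological range \eqn{[-\tau_{max}, \tau_{max}]}.
#'
#' @param inter_ear_distance_m inter-ear distance in meters; the default
#'   0.03 m is a gerbil-like value giving a physiological range of about
#'   +/-112 microseconds.
#' @param sound_speed_m_s speed of sound in m/s.
#' @return object of class `head_geometry` with `tau_max_us`.
#' @export
#' @examples
#' g <- headGeometry()
#' g$tau_max_us
headGeometry <- function(inter_ear_distance_m = 0.03,
                         sound_speed_m_s = 343) {
  stopifnot(inter_ear_distance_m > 0, sound_speed_m_s > 0)
  g <- list(inter_ear_distance_m = inter_ear_distance_m,
            sound_speed_m_s = sound_speed_m_s)
  g$tau_max_us <- 1e6 * inter_ear_distance_m / (2 * sound_speed_m_s) *
    (pi / 2 + 1)
  class(g) <- "head_geometry"
  g
}

#' @export
print.head_geometry <- function(x, ...) {
  cat(sprintf(
    "Head geometry: d = %.3g m, c = %.4g m/s, tau_max = %.1f us\n",
    x$inter_ear_distance_m, x$sound_speed_m_s, x$tau_max_us))
  invisible(x)
}

#' Map interaural angle to ITD
#'
#' @param theta interaural angles in radians, within [-pi/2, pi/2].
#' @param geom a [headGeometry()].
#' @return ITDs in microseconds; odd and strictly increasing in `theta`.
#' @export
angleToItd <- function(theta, geom) {
  if (any(!is.finite(theta)) || any(abs(theta) > pi / 2 + 1e-12))
    stop("theta must lie in [-pi/2, pi/2]")
  1e6 * geom$inter_ear_distance_m / (2 * geom$sound_speed_m_s) *
    (theta + sin(theta))
}

#' Map ITD back to interaural angle
#'
#' Numerical (monotone root-finding) inverse of [angleToItd()].
#'
#' @param tau_us ITDs in microseconds, |tau| <= tau_max.
#' @param geom a [headGeometry()].
#' @return angles in radians.
#' @export
itdToAngle <- function(tau_us, geom) {
  if (any(abs(tau_us) > geom$tau_max_us * (1 + 1e-12)))
    stop("|tau| exceeds tau_max for this geometry")
  vapply(tau_us, function(t1) {
    if (t1 == 0) return(0)
    t1 <- min(max(t1, -geom$tau_max_us), geom$tau_max_us)
    stats::uniroot(function(th) angleToItd(th, geom) - t1,
                   interval = c(-pi / 2, pi / 2),
                   tol = 1e-9 * pi)$root
  }, numeric(1))
}

#' Prior distribution of ITDs from uniformly distributed source angles
#'
#' Sound sources uniform on the sphere (uniform dihedral angle) induce a
#' uniform interaural-angle density on [-pi/2, pi/2]; the ITD prior follows
#' by change of variables through the angle-to-ITD mapping. Each ITD bin's
#' probability is the (normalised) angular measure of its preimage, so the
#' edge singularity of the pointwise Jacobian at +/-tau_max is integrated
#' exactly and the grid density is finite and normalised by construction.
#'
#' @param geom a [headGeometry()].
#' @param n_grid number of ITD bins (>= 16) on [-tau_max, tau_max].
#' @return object of class `itd_prior`: `grid` (bin centers, us), `weights`
#'   (probabilities summing to 1, symmetric in tau), `edges`, `geom`.
#' @export
itdPrior <- function(geom, n_grid = 201L) {
  if (n_grid < 16L) stop("n_grid must be >= 16")
  edges <- seq(-geom$tau_max_us, geom$tau_max_us, length.out = n_grid + 1L)
  th <- itdToAngle(edges, geom)
  w <- diff(th) / pi
  w <- w / sum(w)
  # enforce exact symmetry against root-finder round-off
  w <- (w + rev(w)) / 2
  structure(list(grid = (edges[-1] + edges[-length(edges)]) / 2,
                 weights = w, edges = edges, geom = geom),
            class = "itd_prior")
}

#' @export
print.itd_prior <- function(x, ...) {
  cat(sprintf("ITD prior: %d bins on [%.1f, %.1f] us\n",
              length(x$grid), min(x$edges), max(x$edges)))
  invisible(x)
}

#' Entropy of a discretized ITD prior, in bits
#'
#' @param prior an [itdPrior()].
#' @return entropy in bits; an upper bound for any mutual information
#'   computed on the same ITD grid.
#' @export
priorEntropy <- function(prior) {
  w <- prior$weights[prior$weights > 0]
  -sum(w * log2(w))
}
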