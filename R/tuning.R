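#' Cyclic Gaussian tuning-curve parameters
#'
#' The tone delay function of a binaural neuron -- firing rate as a function
#' of interaural phase difference (IPD) at one stimulus frequency -- is
#' modelled as a Gaussian bump wrapped onto the phase circle:
#' \deqn{r(\phi) = b + a \sum_k \exp\left(-\frac{(\phi - \phi_0 + k)^2}{2 w^2}\right)}
#' with baseline \eqn{b} (Hz), amplitude \eqn{a} (Hz), width \eqn{w}
#' (cycles) and best IPD \eqn{\phi_0} (cycles), the sum running over integer
#' wraps \eqn{k}.
#'
#' @param baseline baseline rate in Hz, >= 0.
#' @param amplitude peak amplitude above baseline in Hz, >= 0.
#' @param width tuning width in cycles, > 0.
#' @param best_ipd IPD of the maximum, in cycles (any real; stored wrapped
#'   to (-0.5, 0.5]).
#' @return an object of class `cyclic_gaussian`.
#' @seealso [evalCyclicGaussian()], [fitToneDelay()]
#' @export
#' @examples
#' p <- cyclicGaussian(10, 50, 0.15, 0.2)
#' evalCyclicGaussian(p, seq(-0.5, 0.5, by = 0.1))
cyclicGaussian <- function(baseline, amplitude, width, best_ipd) {
  stopifnot(is.finite(baseline), is.finite(amplitude), is.finite(width),
            is.finite(best_ipd))
  if (baseline < 0) stop("baseline must be >= 0")
  if (amplitude < 0) stop("amplitude must be >= 0")
  if (width <= 0) stop("width must be > 0")
  structure(
    list(baseline = baseline, amplitude = amplitude, width = width,
         best_ipd = wrapPhase(best_ipd)),
    class = "cyclic_gaussian"
  )
}

#' @export
print.cyclic_gaussian <- function(x, ...) {
  cat(sprintf(
    "Cyclic Gaussian tuning: baseline %.2f Hz, amplitude %.2f Hz, width %.3f cyc, best IPD %.3f cyc\n",
    x$baseline, x$amplitude, x$width, x$best_ipd))
  invisible(x)
}

# raw wrapped-Gaussian sum; dev = ipd - best_ipd (cycles), vectorised
wrappedGaussSum <- function(dev, width, K = 5L) {
  s <- 0
  for (k in -K:K) s <- s + exp(-(dev + k)^2 / (2 * width^2))
  s
}

#' Evaluate a cyclic Gaussian tuning curve
#'
#' @param params a [cyclicGaussian()] object.
#' @param ipd IPD values in cycles (numeric vector).
#' @param K truncation of the wrap sum; the default 5 agrees with a K = 50
#'   reference to better than 1e-6 Hz for widths up to 0.5 cycles.
#' @return firing rates in Hz, same length as `ipd`; always >= baseline.
#' @export
evalCyclicGaussian <- function(params, ipd, K = 5L) {
  if (any(!is.finite(ipd))) stop("ipd must be finite")
  params$baseline + params$amplitude *
    wrappedGaussSum(ipd - params$best_ipd, params$width, K = K)
}

#' Fit a cyclic Gaussian to one tone delay function
#'
#' Rates are averaged over repetitions at each IPD before fitting; the four
#' parameters (baseline, amplitude, width, best IPD) are then estimated by
#' nonlinear least squares with multiple restarts of the best-IPD
#' initialisation.
#'
#' @param ipd IPD values in cycles (frequency x ITD). At least 6 distinct
#'   values spanning at least one full cycle are required.
#' @param rate firing rates in Hz, same length as `ipd` (repetitions appear
#'   as repeated `ipd` entries).
#' @param n_starts number of equally spaced best-IPD initialisations.
#' @param width_bounds allowed tuning width range in cycles.
#' @param flat_tol amplitudes below `flat_tol` times the mean rate (or below
#'   1e-6 Hz absolute) mark the fit as degenerate (flat cell); the cell is
#'   flagged, not dropped.
#' @return a `cyclic_gaussian_fit`: the `cyclic_gaussian` parameters plus
#'   `sse` (residual sum of squares on the repetition-averaged rates),
#'   `degenerate` flag and number of points used.
#' @export
fitToneDelay <- function(ipd, rate, n_starts = 8L,
                         width_bounds = c(0.02, 1.0), flat_tol = 1e-3) {
  stopifnot(length(ipd) == length(rate), all(is.finite(ipd)),
            all(is.finite(rate)))
  # average over repetitions at identical IPD values
  mu <- tapply(rate, ipd, mean)
  x <- as.numeric(names(mu))
  y <- as.numeric(mu)
  if (length(x) < 6L)
    stop("need at least 6 distinct IPD values, got ", length(x))
  if (diff(range(x)) < 1 - 1e-9)
    stop("IPD values must span at least one full cycle")

  obj <- function(p) {
    pr <- p[1] + p[2] * wrappedGaussSum(x - p[4], p[3])
    sum((pr - y)^2)
  }

  b0 <- max(min(y), 0)
  a0 <- max(max(y) - min(y), 1e-3)
  best <- NULL
  for (s in seq_len(n_starts)) {
    phi0 <- -0.5 + (s - 0.5) / n_starts
    fit <- try(stats::optim(
      c(b0, a0, 0.15, phi0), obj, method = "L-BFGS-B",
      lower = c(0, 0, width_bounds[1], phi0 - 0.5),
      upper = c(Inf, Inf, width_bounds[2], phi0 + 0.5),
      control = list(factr = 1e4, maxit = 500)
    ), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) ||
        fit$value < best$value - 1e-12 ||
        (abs(fit$value - best$value) <= 1e-12 &&
         wrapPhase(fit$par[4]) < wrapPhase(best$par[4]))) {
      best <- fit
    }
  }
  if (is.null(best))
    stop("cyclic Gaussian fit failed at every restart")

  p <- best$par
  # guard against optimizer round-off a hair outside the box
  p[1] <- max(p[1], 0)
  p[2] <- max(p[2], 0)
  p[3] <- min(max(p[3], width_bounds[1]), width_bounds[2])
  degenerate <- p[2] < max(flat_tol * mean(y), 1e-6)
  out <- cyclicGaussian(p[1], p[2], p[3], p[4])
  out$sse <- best$value
  out$degenerate <- degenerate
  out$n_points <- length(x)
  class(out) <- c("cyclic_gaussian_fit", "cyclic_gaussian")
  out
}

#' Fit tone delay functions for every (cell, frequency) in a measurement table
#'
#' @param measurements a data.frame with columns `cell_id`, `frequency_hz`,
#'   `itd_us`, `repetition`, and `count` (spikes) or `rate` (Hz).
#' @param duration stimulus duration in seconds, used to convert counts to
#'   rates when `rate` is absent.
#' @return data.frame with one row per (cell, frequency): the fitted
#'   baseline, amplitude, width, best IPD, residual SSE and degeneracy flag.
#' @export
fitAllToneDelays <- function(measurements, duration) {
  stopifnot(all(c("cell_id", "frequency_hz", "itd_us") %in%
                  names(measurements)))
  if (is.null(measurements$rate)) {
    if (is.null(measurements$count))
      stop("measurements need a 'count' or 'rate' column")
    if (any(measurements$count < 0)) stop("counts must be >= 0")
    measurements$rate <- measurements$count / duration
  }
  ipd_all <- measurements$frequency_hz * measurements$itd_us * 1e-6
  key <- interaction(measurements$cell_id, measurements$frequency_hz,
                     drop = TRUE)
  rows <- lapply(split(seq_len(nrow(measurements)), key), function(idx) {
    f <- fitToneDelay(ipd_all[idx], measurements$rate[idx])
    data.frame(
      cell_id = measurements$cell_id[idx[1]],
      frequency_hz = measurements$frequency_hz[idx[1]],
      baseline_hz = f$baseline, amplitude_hz = f$amplitude,
      width_cycles = f$width, best_ipd_cycles = f$best_ipd,
      sse = f$sse, degenerate = f$degenerate,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$cell_id, out$frequency_hz), , drop = FALSE]
}

#' Read / write spike-count measurement tables
#'
#' Plain-CSV interchange format: one row per
#' (cell, frequency, ITD, repetition) with the spike count of that trial.
#'
#' @param path file path.
#' @param measurements data.frame as produced by [generateExperiment()].
#' @return `readMeasurements` returns the data.frame.
#' @export
readMeasurements <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname readMeasurements
#' @export
writeMeasurements <- function(measurements, path) {
  utils::write.csv(measurements, path, row.names = FALSE)
  invisible(path)
}
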