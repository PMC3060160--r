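#' Simulate population rate patterns
#'
#' Draws trial firing rates for every cell at every (ITD, frequency)
#' condition from the clipped-Gaussian noise model around the cell's mean
#' tuning. Trials are independent across cells and conditions (no noise
#' correlations).
#'
#' @param cells a `cell_population`.
#' @param model a [rateNoiseModel()].
#' @param conditions data.frame with columns `itd_us` and `frequency_hz`.
#' @param n_trials trials per condition (>= 1).
#' @param seed integer seed.
#' @return object of class `population_response`: `cells`, `conditions`,
#'   `rates` (array cell x condition x trial, Hz, all >= 0), `seed`.
#' @export
#' @seealso [conditionGrid()], [mirrorPopulation()]
simulatePopulation <- function(cells, model, conditions, n_trials = 10L,
                               seed = 1L) {
  if (n_trials < 1L) stop("n_trials must be >= 1")
  stopifnot(all(c("itd_us", "frequency_hz") %in% names(conditions)))
  n_cell <- nrow(cells)
  n_cond <- nrow(conditions)
  mu <- matrix(0, n_cell, n_cond)
  for (i in seq_len(n_cell)) {
    mu[i, ] <- meanTuning(cells[i, , drop = FALSE],
                          conditions$frequency_hz, conditions$itd_us)
  }
  rates <- withr::with_seed(seed, {
    array(sampleRates(rep(as.vector(mu), n_trials), model,
                      n = n_cell * n_cond * n_trials),
          dim = c(n_cell, n_cond, n_trials))
  })
  structure(list(cells = cells, conditions = conditions, rates = rates,
                 seed = seed),
            class = "population_response")
}

#' @export
print.population_response <- function(x, ...) {
  d <- dim(x$rates)
  cat(sprintf(
    "Population response: %d cells x %d conditions x %d trials (seed %d)\n",
    d[1], d[2], d[3], x$seed))
  invisible(x)
}

#' Build the default (ITD x frequency) condition grid
#'
#' @param geom a [headGeometry()]; ITDs span the physiological range.
#' @param n_itd number of ITD points (default 41).
#' @param frequencies_hz stimulus frequencies (default 5 spanning 800-1000
#'   Hz).
#' @return data.frame with `itd_us` and `frequency_hz`.
#' @export
conditionGrid <- function(geom, n_itd = 41L,
                          frequencies_hz = seq(800, 1000, length.out = 5L)) {
  itd <- seq(-geom$tau_max_us, geom$tau_max_us, length.out = n_itd)
  expand.grid(itd_us = itd, frequency_hz = frequencies_hz,
              KEEP.OUT.ATTRS = FALSE)
}

#' Mirror a population into the opposite hemisphere
#'
#' The opposite hemisphere holds an identical population with mirrored
#' characteristics: CP -> -CP (re-wrapped) and CD -> -CD; best frequencies
#' and tuning shapes are unchanged. Mirroring is an involution, and the
#' mirrored cell's mean tuning at ITD tau equals the original's at -tau.
#'
#' @param cells a `cell_population`.
#' @return the mirrored `cell_population`.
#' @export
mirrorPopulation <- function(cells) {
  out <- cells
  out$cp_cycles <- wrapPhase(-cells$cp_cycles)
  out$cd_ms <- -cells$cd_ms
  out$cd_scaled_cycles <- -cells$cd_scaled_cycles
  out
}
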