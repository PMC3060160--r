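#' Configuration for the virtual DNLL population generator
#'
#' The generator emulates the statistical structure of the recorded gerbil
#' DNLL population: best frequencies flat within the band; characteristic
#' phases broadly distributed over the cycle with a positive bias; CDs
#' peaking at zero and skewed negative; and -- the structural core -- the
#' cells clustering along a constant-best-phase line in the (CP, CD*BF)
#' plane. Each cell first draws its best phase BP around
#' `mean_best_phase`, then a broad CP, and sets CD*BF = BP - CP (plus
#' jitter), which induces the negative circular-linear CP-CD correlation.
#'
#' @param n_cells number of cells (default 153).
#' @param bf_band best-frequency band in Hz (default 800-1000, uniform).
#' @param mean_best_phase mean of the best-phase cluster, cycles.
#' @param best_phase_spread SD of the best-phase cluster, cycles.
#' @param cd_jitter_ms SD of additional CD jitter, ms.
#' @param cp_uniform_weight mixture weight of the broad uniform CP
#'   component (the rest is a wrapped Gaussian with positive mean).
#' @param cp_bias_mean,cp_bias_sd wrapped-Gaussian CP component, cycles.
#' @param baseline_mean_hz,baseline_sd_hz,amplitude_mean_hz,amplitude_sd_hz,width_mean_cycles,width_sd_cycles
#'   tuning-shape distributions (Gaussians, truncated to valid ranges).
#' @return list of class `population_generator_config`.
#' @export
populationGeneratorConfig <- function(n_cells = 153L,
                                      bf_band = c(800, 1000),
                                      mean_best_phase = 0.2,
                                      best_phase_spread = 0.1,
                                      cd_jitter_ms = 0.05,
                                      cp_uniform_weight = 0.5,
                                      cp_bias_mean = 0.2,
                                      cp_bias_sd = 0.15,
                                      baseline_mean_hz = 20,
                                      baseline_sd_hz = 8,
                                      amplitude_mean_hz = 50,
                                      amplitude_sd_hz = 15,
                                      width_mean_cycles = 0.25,
                                      width_sd_cycles = 0.05) {
  stopifnot(n_cells >= 1, bf_band[2] > bf_band[1],
            best_phase_spread >= 0, cd_jitter_ms >= 0,
            cp_uniform_weight >= 0, cp_uniform_weight <= 1)
  structure(as.list(environment()),
            class = "population_generator_config")
}

#' Generate a virtual cell population
#'
#' @param config a [populationGeneratorConfig()].
#' @param seed integer seed (identical seeds give identical populations).
#' @return a `cell_population` of `config$n_cells` cells.
#' @export
#' @examples
#' cells <- generatePopulation(populationGeneratorConfig(n_cells = 20), seed = 7)
#' populationCpCdStats(cells)$vs_cd_scaled$r
generatePopulation <- function(config, seed = 1L) {
  n <- config$n_cells
  withr::with_seed(seed, {
    bf <- stats::runif(n, config$bf_band[1], config$bf_band[2])
    bp <- stats::rnorm(n, config$mean_best_phase, config$best_phase_spread)
    from_unif <- stats::runif(n) < config$cp_uniform_weight
    cp <- ifelse(from_unif,
                 stats::runif(n, -0.5, 0.5),
                 wrapPhase(stats::rnorm(n, config$cp_bias_mean,
                                        config$cp_bias_sd)))
    cds <- bp - cp + stats::rnorm(n, 0, config$cd_jitter_ms * 1e-3) * bf
    baseline <- pmax(stats::rnorm(n, config$baseline_mean_hz,
                                  config$baseline_sd_hz), 0)
    amplitude <- pmax(stats::rnorm(n, config$amplitude_mean_hz,
                                   config$amplitude_sd_hz), 1)
    width <- pmin(pmax(stats::rnorm(n, config$width_mean_cycles,
                                    config$width_sd_cycles), 0.05), 0.5)
    cellPopulation(
      cell_id = sprintf("synth_%03d", seq_len(n)),
      bf_hz = bf, cp_cycles = cp, cd_ms = cds / bf * 1e3,
      baseline_hz = baseline, amplitude_hz = amplitude,
      width_cycles = width)
  })
}

#' Band-average tuning shape of a population
#'
#' Element-wise mean of the cells' baseline, amplitude and width: the
#' shape used for MI landscapes.
#'
#' @param cells a `cell_population`.
#' @return a [cyclicGaussian()] with best IPD 0.
#' @export
averageShape <- function(cells) {
  cyclicGaussian(mean(cells$baseline_hz), mean(cells$amplitude_hz),
                 mean(cells$width_cycles), 0)
}

#' Emulate the tone-delay measurement protocol on virtual cells
#'
#' For each cell, 5 pure-tone frequencies are log-spaced over
#' `octave_span` octaves centred on BF; for each frequency, ITDs span
#' `itd_span_cycles` cycles of that frequency; every condition is repeated
#' `n_reps` times with spike counts drawn from the noise model around the
#' cell's mean tuning (counts = rate draws times duration, rounded,
#' nonnegative).
#'
#' @param cells a `cell_population`.
#' @param model a [rateNoiseModel()].
#' @param n_frequencies frequencies per cell (default 5).
#' @param octave_span frequency span in octaves (default 0.5).
#' @param itd_span_cycles ITD span per frequency in stimulus cycles
#'   (>= 1).
#' @param n_itd ITD points per frequency (default 24).
#' @param n_reps repetitions per condition (>= 3).
#' @param seed integer seed.
#' @return measurement data.frame: `cell_id`, `frequency_hz`, `itd_us`,
#'   `repetition`, `count`, `rate`.
#' @export
generateExperiment <- function(cells, model, n_frequencies = 5L,
                               octave_span = 0.5, itd_span_cycles = 1,
                               n_itd = 24L, n_reps = 3L, seed = 1L) {
  if (itd_span_cycles < 1) stop("itd_span_cycles must be >= 1")
  if (n_reps < 1L) stop("n_reps must be >= 1")
  withr::with_seed(seed, {
    tabs <- lapply(seq_len(nrow(cells)), function(i) {
      cell <- cells[i, , drop = FALSE]
      freqs <- cell$bf_hz *
        2^seq(-octave_span / 2, octave_span / 2,
              length.out = n_frequencies)
      per_f <- lapply(freqs, function(f) {
        itd <- seq(-itd_span_cycles / 2, itd_span_cycles / 2,
                   length.out = n_itd) / f * 1e6
        grid <- expand.grid(itd_us = itd, repetition = seq_len(n_reps),
                            KEEP.OUT.ATTRS = FALSE)
        mu <- meanTuning(cell, f, grid$itd_us)
        r <- sampleRates(mu, model, n = nrow(grid))
        count <- pmax(round(r * model$duration), 0)
        data.frame(cell_id = cell$cell_id, frequency_hz = f,
                   itd_us = grid$itd_us, repetition = grid$repetition,
                   count = count, rate = count / model$duration,
                   stringsAsFactors = FALSE)
      })
      do.call(rbind, per_f)
    })
    out <- do.call(rbind, tabs)
    rownames(out) <- NULL
    out
  })
}

#' Jitter characteristic phases and scaled delays
#'
#' Adds independent Gaussian jitter to each cell's CP (re-wrapped) and
#' CD*BF; BFs and shapes are untouched, CD is recovered via each cell's
#' BF. Used to probe the robustness of the linear bilateral difference
#' code against measurement uncertainty in the characteristics.
#'
#' @param cells a `cell_population`.
#' @param sd_cp CP jitter SD in cycles (>= 0).
#' @param sd_cds CD*BF jitter SD in cycles (>= 0).
#' @param seed integer seed.
#' @return the jittered `cell_population`.
#' @export
jitterCharacteristics <- function(cells, sd_cp, sd_cds, seed = 1L) {
  stopifnot(sd_cp >= 0, sd_cds >= 0)
  n <- nrow(cells)
  withr::with_seed(seed, {
    out <- cells
    out$cp_cycles <- wrapPhase(cells$cp_cycles + stats::rnorm(n, 0, sd_cp))
    out$cd_scaled_cycles <- cells$cd_scaled_cycles +
      stats::rnorm(n, 0, sd_cds)
    out$cd_ms <- out$cd_scaled_cycles / out$bf_hz * 1e3
    out
  })
}
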