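#' Construct a cell population table
#'
#' The atom of all analyses is one neuron's set of characteristics: best
#' frequency (BF), characteristic phase (CP, cycles), characteristic delay
#' (CD, ms), the frequency-scaled delay CD*BF (cycles), the
#' frequency-averaged cyclic-Gaussian shape (baseline, amplitude, width) and
#' the mean resultant length of the circular-linear fit. A population is a
#' data.frame of class `cell_population` with one row per cell.
#'
#' The best-IPD model is \eqn{\phi_{best}(f) = CP + CD \cdot f}: CP is the
#' intercept and CD the slope of the phase-frequency line. Positive ITD/IPD
#' means contralateral-leading.
#'
#' @param cell_id identifiers (unique).
#' @param bf_hz best frequencies in Hz.
#' @param cp_cycles characteristic phases in cycles; wrapped to (-0.5, 0.5].
#' @param cd_ms characteristic delays in milliseconds.
#' @param baseline_hz,amplitude_hz,width_cycles frequency-averaged
#'   cyclic-Gaussian shape parameters.
#' @param resultant_length mean resultant length of the circular-linear fit,
#'   in [0, 1] (NA when unknown, e.g. for generated populations).
#' @return a `cell_population` data.frame; `cd_scaled_cycles` is derived as
#'   `cd_ms * 1e-3 * bf_hz`.
#' @export
cellPopulation <- function(cell_id, bf_hz, cp_cycles, cd_ms,
                           baseline_hz, amplitude_hz, width_cycles,
                           resultant_length = NA_real_) {
  n <- length(cell_id)
  stopifnot(length(bf_hz) == n, length(cp_cycles) == n, length(cd_ms) == n)
  if (anyDuplicated(cell_id)) stop("cell_id must be unique")
  if (any(bf_hz <= 0)) stop("bf_hz must be positive")
  if (any(baseline_hz < 0) || any(amplitude_hz < 0) || any(width_cycles <= 0))
    stop("invalid shape parameters")
  rl <- rep_len(resultant_length, n)
  if (any(!is.na(rl) & (rl < 0 | rl > 1)))
    stop("resultant_length must lie in [0, 1]")
  out <- data.frame(
    cell_id = cell_id,
    bf_hz = bf_hz,
    cp_cycles = wrapPhase(cp_cycles),
    cd_ms = cd_ms,
    cd_scaled_cycles = cd_ms * 1e-3 * bf_hz,
    baseline_hz = rep_len(baseline_hz, n),
    amplitude_hz = rep_len(amplitude_hz, n),
    width_cycles = rep_len(width_cycles, n),
    resultant_length = rl,
    stringsAsFactors = FALSE
  )
  class(out) <- c("cell_population", "data.frame")
  out
}

#' @export
print.cell_population <- function(x, ...) {
  cat(sprintf("Cell population: %d neurons, BF %.0f-%.0f Hz\n",
              nrow(x), min(x$bf_hz), max(x$bf_hz)))
  cat(sprintf("  CP (cycles): median %.3f [%.3f, %.3f]\n",
              stats::median(x$cp_cycles), min(x$cp_cycles), max(x$cp_cycles)))
  cat(sprintf("  CD (ms):     median %.3f [%.3f, %.3f]\n",
              stats::median(x$cd_ms), min(x$cd_ms), max(x$cd_ms)))
  n_show <- min(nrow(x), 5L)
  print.data.frame(utils::head(as.data.frame(x), n_show), digits = 4)
  if (nrow(x) > n_show)
    cat(sprintf("  ... and %d more cells\n", nrow(x) - n_show))
  invisible(x)
}

# keep the class through subsetting
#' @export
`[.cell_population` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) class(out) <- c("cell_population", "data.frame")
  out
}

#' Mean tone-delay tuning of one cell at given frequency and ITD
#'
#' Evaluates the cell's cyclic Gaussian at IPD = f * tau with best IPD
#' CP + CD * f.
#'
#' @param cell one-row `cell_population` (or list with the same fields).
#' @param frequency_hz stimulus frequency in Hz (scalar).
#' @param itd_us ITD values in microseconds (vector).
#' @return mean firing rates in Hz.
#' @export
meanTuning <- function(cell, frequency_hz, itd_us) {
  ipd <- frequency_hz * itd_us * 1e-6
  bp <- cell$cp_cycles + cell$cd_ms * 1e-3 * frequency_hz
  cell$baseline_hz + cell$amplitude_hz *
    wrappedGaussSum(ipd - bp, cell$width_cycles)
}

#' Read / write cell characteristics tables
#'
#' CSV columns: cell_id, bf_hz, cp_cycles, cd_ms, cd_scaled_cycles,
#' baseline_hz, amplitude_hz, width_cycles, resultant_length.
#'
#' @param path file path.
#' @param cells a `cell_population`.
#' @return `readCells` returns a `cell_population`.
#' @export
readCells <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  cellPopulation(x$cell_id, x$bf_hz, x$cp_cycles, x$cd_ms,
                 x$baseline_hz, x$amplitude_hz, x$width_cycles,
                 x$resultant_length)
}

#' @rdname readCells
#' @export
writeCells <- function(cells, path) {
  utils::write.csv(as.data.frame(cells), path, row.names = FALSE)
  invisible(path)
}
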