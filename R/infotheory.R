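#' Rate discretisation grid for information calculations
#'
#' Bins cover [0, baseline + amplitude + 6 sigma_max], where sigma_max is
#' the model rate SD at the peak mean rate, so essentially all conditional
#' mass lies on the grid.
#'
#' @param shape a [cyclicGaussian()] (the cell's shape; `best_ipd` ignored).
#' @param model a [rateNoiseModel()].
#' @param n_rate number of rate bins.
#' @return list with `edges` (length n_rate + 1) and `centers`.
#' @export
rateGrid <- function(shape, model, n_rate = 200L) {
  rmax <- shape$baseline + shape$amplitude
  upper <- rmax + 6 * rateSd(model, rmax)
  edges <- seq(0, upper, length.out = n_rate + 1L)
  list(edges = edges, centers = (edges[-1] + edges[-length(edges)]) / 2)
}

# binned conditional probability P(rate bin | mean), exact via the Gaussian
# CDF on the bin edges; tail mass above the top edge folds into the last bin
binnedRateProbs <- function(mean_rate, model, edges) {
  s <- rateSd(model, mean_rate)
  cdf <- stats::pnorm(edges, mean_rate, s)
  p <- diff(cdf)
  p[length(p)] <- p[length(p)] + (1 - cdf[length(cdf)])
  if (model$clip == "renormalize") {
    p <- p / (1 - cdf[1])
  } else {
    p[1] <- p[1] + cdf[1]
  }
  p / sum(p)
}

# vectorised over a vector of means: returns a length(mu) x n_bin matrix
binnedRateProbsMatrix <- function(mu, model, edges) {
  s <- rateSd(model, mu)
  z <- (matrix(edges, length(mu), length(edges), byrow = TRUE) - mu) / s
  cdf <- stats::pnorm(z)
  p <- cdf[, -1, drop = FALSE] - cdf[, -ncol(cdf), drop = FALSE]
  p[, ncol(p)] <- p[, ncol(p)] + (1 - cdf[, ncol(cdf)])
  if (model$clip == "renormalize") {
    p <- p / (1 - cdf[, 1])
  } else {
    p[, 1] <- p[, 1] + cdf[, 1]
  }
  p / rowSums(p)
}

#' Conditional rate distribution at a given ITD, averaged over frequency
#'
#' The cell's mean tuning at frequency f and ITD tau is the cyclic Gaussian
#' evaluated at IPD = f tau with best IPD CP + CD f; the conditional rate
#' distribution is the frequency-weighted mixture of the clipped Gaussians
#' around those means.
#'
#' @param tau_us ITD in microseconds (scalar).
#' @param cell one-row `cell_population`.
#' @param model a [rateNoiseModel()].
#' @param frequencies_hz stimulus frequencies in Hz.
#' @param weights frequency weights (normalised internally); default
#'   uniform.
#' @param grid a [rateGrid()]; default built from the cell's shape.
#' @return probability vector over the rate bins (sums to 1).
#' @export
conditionalDensityGivenItd <- function(tau_us, cell, model, frequencies_hz,
                                       weights = NULL, grid = NULL) {
  if (length(frequencies_hz) == 0L) stop("empty frequency set")
  if (is.null(weights)) weights <- rep(1, length(frequencies_hz))
  weights <- weights / sum(weights)
  if (is.null(grid))
    grid <- rateGrid(cyclicGaussian(cell$baseline_hz, cell$amplitude_hz,
                                    cell$width_cycles, 0), model)
  p <- 0
  for (i in seq_along(frequencies_hz)) {
    mu <- meanTuning(cell, frequencies_hz[i], tau_us)
    p <- p + weights[i] * binnedRateProbs(mu, model, grid$edges)
  }
  p / sum(p)
}

#' Frequency weights: uniform or power-law
#'
#' @param frequencies_hz frequency set in Hz.
#' @param scheme "uniform" or "power_law".
#' @param exponent power-law exponent alpha in w ~ f^(-alpha) (default 1,
#'   pink-noise-like emphasis of low frequencies).
#' @return normalised weights.
#' @export
frequencyWeights <- function(frequencies_hz,
                             scheme = c("uniform", "power_law"),
                             exponent = 1) {
  scheme <- match.arg(scheme)
  w <- switch(scheme,
              uniform = rep(1, length(frequencies_hz)),
              power_law = frequencies_hz^(-exponent))
  w / sum(w)
}

#' Mutual information between ITD and single-cell firing rate
#'
#' Discretised quadrature of
#' \deqn{I = \sum_\tau p(\tau) \sum_r p(r|\tau) \log_2 \frac{p(r|\tau)}{p(r)}}
#' with the ITD prior from the head geometry and the conditional rate
#' distribution marginalised over stimulus frequency.
#'
#' @param cell one-row `cell_population`.
#' @param model a [rateNoiseModel()].
#' @param prior an [itdPrior()] (sets the ITD grid and p(tau)).
#' @param frequencies_hz stimulus frequencies in Hz.
#' @param weights frequency weights; default uniform.
#' @param n_rate number of rate bins.
#' @param convergence_check recompute with both grids doubled and flag
#'   whether the change is below 0.01 bits.
#' @return MI in bits (scalar, >= 0). With `convergence_check = TRUE` the
#'   result carries attributes `converged` and `delta_bits`.
#' @export
mutualInformation <- function(cell, model, prior, frequencies_hz,
                              weights = NULL, n_rate = 200L,
                              convergence_check = FALSE) {
  if (abs(sum(prior$weights) - 1) > 1e-8) stop("prior is not normalised")
  grid <- rateGrid(cyclicGaussian(cell$baseline_hz, cell$amplitude_hz,
                                  cell$width_cycles, 0), model, n_rate)
  if (is.null(weights)) weights <- rep(1, length(frequencies_hz))
  weights <- weights / sum(weights)

  n_tau <- length(prior$grid)
  cond <- matrix(0, n_tau, n_rate)
  for (i in seq_along(frequencies_hz)) {
    mu <- meanTuning(cell, frequencies_hz[i], prior$grid)
    cond <- cond + weights[i] * binnedRateProbsMatrix(mu, model, grid$edges)
  }
  cond <- cond / rowSums(cond)
  p_r <- as.numeric(crossprod(prior$weights, cond))
  ratio <- sweep(cond, 2, p_r, "/")
  term <- cond * log2(pmax(ratio, .Machine$double.xmin))
  term[cond == 0] <- 0
  mi <- max(sum(prior$weights * rowSums(term)), 0)
  if (convergence_check) {
    prior2 <- itdPrior(prior$geom, 2L * n_tau)
    mi2 <- mutualInformation(cell, model, prior2, frequencies_hz, weights,
                             n_rate = 2L * n_rate)
    attr(mi, "delta_bits") <- abs(mi2 - mi)
    attr(mi, "converged") <- abs(mi2 - mi) < 0.01
  }
  mi
}

# build a one-row synthetic cell at (cp, cds) with a fixed shape and BF
syntheticCell <- function(cp, cds, shape, bf_hz, id = "synth") {
  cellPopulation(cell_id = id, bf_hz = bf_hz, cp_cycles = cp,
                 cd_ms = cds / bf_hz * 1e3,
                 baseline_hz = shape$baseline, amplitude_hz = shape$amplitude,
                 width_cycles = shape$width)
}

#' Mutual-information landscape over (CP, CD*BF)
#'
#' MI of synthetic cells with the band-average tuning shape, evaluated at
#' every grid point of characteristic phase and frequency-scaled
#' characteristic delay (CD is recovered as CD*BF divided by the band
#' centre frequency).
#'
#' @param shape band-average [cyclicGaussian()] shape.
#' @param model a [rateNoiseModel()].
#' @param prior an [itdPrior()].
#' @param cp_grid CP values in cycles.
#' @param cds_grid CD*BF values in cycles.
#' @param bf_hz band centre frequency in Hz.
#' @param frequencies_hz stimulus frequencies (default 5 spanning the
#'   800-1000 Hz band).
#' @param weights frequency weights.
#' @param n_rate rate bins per MI evaluation.
#' @return object of class `mi_landscape`: `cp_grid`, `cds_grid`, `mi`
#'   (matrix cp x cds, bits) and a `settings` list.
#' @export
miLandscape <- function(shape, model, prior,
                        cp_grid = seq(-0.5, 0.5, length.out = 41L),
                        cds_grid = seq(-1, 1, length.out = 41L),
                        bf_hz = 900,
                        frequencies_hz = seq(800, 1000, length.out = 5L),
                        weights = NULL, n_rate = 200L) {
  mi <- matrix(NA_real_, length(cp_grid), length(cds_grid))
  for (j in seq_along(cds_grid)) {
    for (i in seq_along(cp_grid)) {
      cell <- syntheticCell(cp_grid[i], cds_grid[j], shape, bf_hz)
      mi[i, j] <- mutualInformation(cell, model, prior, frequencies_hz,
                                    weights, n_rate = n_rate)
    }
  }
  structure(list(cp_grid = cp_grid, cds_grid = cds_grid, mi = mi,
                 settings = list(shape = shape, model = model,
                                 geom = prior$geom,
                                 n_tau = length(prior$grid),
                                 n_rate = n_rate, bf_hz = bf_hz,
                                 frequencies_hz = frequencies_hz,
                                 weights = weights)),
            class = "mi_landscape")
}

#' @export
print.mi_landscape <- function(x, ...) {
  s <- landscapeSummary(x)
  cat(sprintf(
    "MI landscape %dx%d: max %.3f bits at (CP %.3f, CD*BF %.3f)\n",
    length(x$cp_grid), length(x$cds_grid), s$max_mi, s$cp_at_max,
    s$cds_at_max))
  invisible(x)
}

#' Location and value of the landscape maximum
#'
#' @param landscape an [miLandscape()].
#' @return list `max_mi` (bits), `cp_at_max`, `cds_at_max` (cycles).
#' @export
landscapeSummary <- function(landscape) {
  ij <- arrayInd(which.max(landscape$mi), dim(landscape$mi))
  list(max_mi = max(landscape$mi),
       cp_at_max = landscape$cp_grid[ij[1]],
       cds_at_max = landscape$cds_grid[ij[2]])
}

#' Write a landscape as CSV plus a JSON settings sidecar
#'
#' @param landscape an [miLandscape()].
#' @param path CSV path; settings go to `paste0(path, ".json")` when
#'   jsonlite is available.
#' @return invisibly, the CSV path.
#' @export
writeLandscape <- function(landscape, path) {
  df <- expand.grid(cp = landscape$cp_grid, cds = landscape$cds_grid)
  df$mi_bits <- as.vector(landscape$mi)
  utils::write.csv(df, path, row.names = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    st <- landscape$settings
    jsonlite::write_json(
      list(n_tau = st$n_tau, n_rate = st$n_rate, bf_hz = st$bf_hz,
           frequencies_hz = st$frequencies_hz,
           inter_ear_distance_m = st$geom$inter_ear_distance_m,
           sound_speed_m_s = st$geom$sound_speed_m_s,
           v1 = st$model$v1, v2 = st$model$v2,
           duration_s = st$model$duration,
           noise_scale = st$model$noise_scale),
      paste0(path, ".json"), auto_unbox = TRUE)
  }
  invisible(path)
}

#' Landscape sweeps over geometry, stimulus length or noise level
#'
#' Recomputes the MI landscape for each value of one swept parameter.
#' Sweeping `inter_ear_distance` rebuilds the prior (and physiological
#' range). Sweeping `duration` rescales the variance law so that the
#' Poisson-consistent count noise of the shorter observation window is
#' preserved (v1 is multiplied by T_ref/T, keeping v1 v2 = 1/T).
#' Sweeping `noise_scale` multiplies the variance law directly.
#'
#' @param parameter one of "inter_ear_distance", "duration", "noise_scale".
#' @param values positive parameter values (meters, seconds, or unitless).
#' @param shape,model,geom base settings; `geom` a [headGeometry()].
#' @param n_tau ITD bins for the rebuilt priors.
#' @param ... passed to [miLandscape()] (grids, frequencies, n_rate).
#' @return list with `landscapes` (one [miLandscape()] per value) and
#'   `summary` (data.frame: value, max_mi, cp_at_max, cds_at_max).
#' @export
sweepLandscape <- function(parameter = c("inter_ear_distance", "duration",
                                         "noise_scale"),
                           values, shape, model, geom, n_tau = 201L, ...) {
  parameter <- match.arg(parameter)
  if (any(values <= 0)) stop("sweep values must be positive")
  landscapes <- vector("list", length(values))
  for (i in seq_along(values)) {
    v <- values[i]
    g <- geom
    m <- model
    if (parameter == "inter_ear_distance") {
      g <- headGeometry(v, geom$sound_speed_m_s)
    } else if (parameter == "duration") {
      m <- rateNoiseModel(model$v1 * model$duration / v, model$v2,
                          duration = v, noise_scale = model$noise_scale,
                          clip = model$clip)
    } else {
      m <- rateNoiseModel(model$v1, model$v2, duration = model$duration,
                          noise_scale = v, clip = model$clip)
    }
    landscapes[[i]] <- miLandscape(shape, m, itdPrior(g, n_tau), ...)
  }
  summaries <- lapply(landscapes, landscapeSummary)
  summary <- data.frame(
    value = values,
    max_mi = vapply(summaries, `[[`, numeric(1), "max_mi"),
    cp_at_max = vapply(summaries, `[[`, numeric(1), "cp_at_max"),
    cds_at_max = vapply(summaries, `[[`, numeric(1), "cds_at_max"))
  list(landscapes = landscapes, summary = summary)
}

#' Shuffle controls for the population's MI distribution
#'
#' Control A shuffles the tuning-shape parameters across cells while
#' keeping each cell's (CP, CD); control B shuffles the (CP, CD) pairs
#' across cells while keeping the shapes. The pooled shuffled MI
#' distributions are compared with the real one by the two-sample
#' Kolmogorov-Smirnov statistic.
#'
#' @param cells a `cell_population` (>= 5 cells).
#' @param model a [rateNoiseModel()].
#' @param prior an [itdPrior()].
#' @param frequencies_hz stimulus frequencies.
#' @param n_shuffles shuffles per control (default 1000).
#' @param seed integer seed.
#' @param ... passed to [mutualInformation()].
#' @return list with `mi_real`, `mi_shuffled_shape` (control A),
#'   `mi_shuffled_cpcd` (control B), and KS comparisons `ks_shape`,
#'   `ks_cpcd` (statistic and p-value each).
#' @export
shuffleAnalysis <- function(cells, model, prior, frequencies_hz,
                            n_shuffles = 1000L, seed = 1L, ...) {
  if (nrow(cells) < 5L) stop("need at least 5 cells")
  if (n_shuffles < 2L) stop("n_shuffles must be >= 2")
  n <- nrow(cells)
  mi_of <- function(pop) {
    vapply(seq_len(nrow(pop)), function(i) {
      mutualInformation(pop[i, , drop = FALSE], model, prior,
                        frequencies_hz, ...)
    }, numeric(1))
  }
  mi_real <- mi_of(cells)
  shape_cols <- c("baseline_hz", "amplitude_hz", "width_cycles")
  mi_a <- mi_b <- numeric(0)
  withr::with_seed(seed, {
    for (s in seq_len(n_shuffles)) {
      perm <- sample.int(n)
      a <- cells
      a[, shape_cols] <- cells[perm, shape_cols]
      b <- cells
      b$cp_cycles <- cells$cp_cycles[perm]
      b$cd_ms <- cells$cd_ms[perm]
      b$cd_scaled_cycles <- b$cd_ms * 1e-3 * b$bf_hz
      mi_a <- c(mi_a, mi_of(a))
      mi_b <- c(mi_b, mi_of(b))
    }
  })
  ks_a <- suppressWarnings(stats::ks.test(mi_real, mi_a))
  ks_b <- suppressWarnings(stats::ks.test(mi_real, mi_b))
  list(mi_real = mi_real, mi_shuffled_shape = mi_a, mi_shuffled_cpcd = mi_b,
       ks_shape = list(statistic = unname(ks_a$statistic),
                       p_value = ks_a$p.value),
       ks_cpcd = list(statistic = unname(ks_b$statistic),
                      p_value = ks_b$p.value))
}

#' Manipulate the population's (CP, CD*BF) configuration
#'
#' `set_cp_zero` zeroes all CPs (idealised delay-line population) leaving
#' CDs untouched; `rotate` rotates every cell's (CP, CD*BF) position vector
#' about the origin by `angle` radians (both coordinates in cycles, CP
#' re-wrapped afterwards); `shuffle_cp` permutes the CPs across cells.
#' Best frequencies and tuning shapes are never modified; CD is recovered
#' from the manipulated CD*BF through each cell's own BF.
#'
#' @param cells a `cell_population`.
#' @param manipulation one of "set_cp_zero", "rotate", "shuffle_cp".
#' @param angle rotation angle in radians (for "rotate").
#' @param seed integer seed (for "shuffle_cp").
#' @return the manipulated `cell_population`.
#' @export
manipulateCharacteristics <- function(cells,
                                      manipulation = c("set_cp_zero",
                                                       "rotate",
                                                       "shuffle_cp"),
                                      angle = NULL, seed = NULL) {
  manipulation <- match.arg(manipulation)
  out <- cells
  if (manipulation == "set_cp_zero") {
    out$cp_cycles <- 0
  } else if (manipulation == "rotate") {
    if (is.null(angle)) stop("rotate needs an angle")
    cp <- cells$cp_cycles
    cds <- cells$cd_scaled_cycles
    out$cp_cycles <- wrapPhase(cos(angle) * cp - sin(angle) * cds)
    out$cd_scaled_cycles <- sin(angle) * cp + cos(angle) * cds
    out$cd_ms <- out$cd_scaled_cycles / out$bf_hz * 1e3
  } else {
    if (is.null(seed)) stop("shuffle_cp needs a seed")
    out$cp_cycles <- withr::with_seed(
      seed, cells$cp_cycles[sample.int(nrow(cells))])
  }
  out
}

#' Plot an MI landscape
#'
#' Grey-level image of MI over the (CP, CD*BF) plane, optionally overlaying
#' a cell population's scatter.
#'
#' @param x an [miLandscape()].
#' @param cells optional `cell_population` to overlay.
#' @param ... passed to [graphics::image()].
#' @return invisibly, `x`.
#' @export
plot.mi_landscape <- function(x, cells = NULL, ...) {
  graphics::image(x$cp_grid, x$cds_grid, x$mi,
                  col = grey.colors(64, start = 0, end = 1),
                  xlab = "characteristic phase (cycles)",
                  ylab = "CD x BF (cycles)",
                  main = "mutual information (bits)", useRaster = TRUE,
                  ...)
  if (!is.null(cells))
    graphics::points(cells$cp_cycles, cells$cd_scaled_cycles, pch = 21,
                     bg = "white")
  invisible(x)
}
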