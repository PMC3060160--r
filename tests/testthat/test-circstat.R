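test_that("circular-linear regression solves the antiphasic and pure-delay-line cells", {
  f <- seq(600, 1000, length.out = 5)
  # trougher: best IPD 0.5 at every frequency -> CP 0.5, CD 0, R_V 1
  fit <- circLinearFit(f, rep(0.5, 5))
  expect_equal(fit$slope, 0)
  expect_equal(fit$offset, 0.5)
  expect_equal(fit$resultant_length, 1)
  # Jeffress delay line: phase = 0.3 ms * f -> CD 0.3 ms, CP 0
  fit2 <- circLinearFit(f, wrapPhase(f * 0.3e-3))
  expect_equal(fit2$slope * 1e3, 0.3, tolerance = 1e-6)
  expect_lt(abs(fit2$offset), 1e-6)
})

test_that("maximised slope agrees with an independent dense-grid oracle", {
  withr::with_seed(31, {
    f <- seq(600, 1000, length.out = 7)
    phi <- wrapPhase(0.13 - 4.3e-4 * f + rnorm(7, 0, 0.04))
  })
  fit <- circLinearFit(f, phi)
  # independent oracle: exhaustive R_V on a 10 us grid
  grid <- seq(-3e-3, 3e-3, by = 1e-5)
  rv <- vapply(grid, function(m) Mod(mean(exp(2i * pi * (phi - m * f)))),
               numeric(1))
  expect_lt(abs(fit$slope - grid[which.max(rv)]), 1e-5 + 1e-9)
  expect_gte(fit$resultant_length, max(rv))
})

test_that("circular-linear fit is equivariant under phase shifts and x rescaling", {
  withr::with_seed(32, {
    x <- seq(600, 1000, length.out = 6)
    phi <- wrapPhase(0.05 + 2.5e-4 * x + rnorm(6, 0, 0.03))
  })
  base <- circLinearFit(x, phi)
  shifted <- circLinearFit(x, wrapPhase(phi + 0.21))
  expect_lt(abs(shifted$slope - base$slope), 1e-9)
  expect_lt(abs(circDiffCycles(shifted$offset, base$offset + 0.21)), 1e-6)
  scaled <- circLinearFit(x / 2, phi, slope_range = c(-6e-3, 6e-3),
                          grid_step = 2e-5)
  expect_lt(abs(scaled$slope - 2 * base$slope), 1e-8)
  # R_V is a mean resultant length: bounded by [0, 1]
  expect_gte(base$resultant_length, 0)
  expect_lte(base$resultant_length, 1)
  expect_error(circLinearFit(rep(1, 4), rep(0.2, 4)), "degenerate")
  expect_warning(circLinearFit(x, wrapPhase(x * 2.99e-3)), "aliasing")
})

test_that("cell characterisation recovers CP/CD and averages shape across frequency", {
  f <- seq(760, 1070, length.out = 5)
  fits <- data.frame(
    cell_id = "c1", frequency_hz = f,
    best_ipd_cycles = wrapPhase(0.1 - 2e-4 * f),
    baseline_hz = c(10, 12, 14, 16, 18), amplitude_hz = 50,
    width_cycles = 0.2)
  cell <- characterizeCell(fits, bf = 900)
  expect_lt(abs(circDiffCycles(cell$cp_cycles, 0.1)), 0.02)
  expect_lt(abs(cell$cd_ms - (-0.2)), 0.02)
  expect_equal(cell$cd_scaled_cycles, cell$cd_ms * 1e-3 * 900)
  expect_equal(cell$baseline_hz, 14)
  expect_gt(cell$cp_cycles, -0.5)
  expect_lte(cell$cp_cycles, 0.5)
})

test_that("population CP-CD statistics recover a constructed line and reject degenerate input", {
  withr::with_seed(41, {
    cd <- runif(40, -0.4, 0.4)   # phases span well under one wrap
    cells <- cellPopulation(
      cell_id = paste0("c", 1:40), bf_hz = runif(40, 800, 1000),
      cp_cycles = wrapPhase(0.2 - cd / 2), cd_ms = cd,
      baseline_hz = 20, amplitude_hz = 50, width_cycles = 0.25)
  })
  st <- populationCpCdStats(cells)
  # cells sit on CP = 0.2 - CD/(2 ms per cycle)
  expect_equal(abs(st$vs_cd$ms_per_cycle), 2, tolerance = 0.01)
  expect_gt(st$vs_cd$r, 0.9)
  expect_lt(st$vs_cd$p_value, 1e-6)
  expect_equal(st$vs_cd$resultant_length, 1, tolerance = 1e-6)
  expect_error(populationCpCdStats(cells[1, ]), "at least 5")
})

test_that("shuffling CPs across cells destroys the circular-linear correlation", {
  withr::with_seed(42, {
    cd <- runif(25, -1.5, 1.5)
    cells <- cellPopulation(
      cell_id = paste0("c", 1:25), bf_hz = runif(25, 800, 1000),
      cp_cycles = wrapPhase(0.2 - cd / 2 + rnorm(25, 0, 0.05)),
      cd_ms = cd, baseline_hz = 20, amplitude_hz = 50,
      width_cycles = 0.25)
  })
  n_sig <- 0L
  for (s in 1:100) {
    shuf <- manipulateCharacteristics(cells, "shuffle_cp", seed = s)
    p <- circLinearCorrelation(shuf$cp_cycles, shuf$cd_ms)$p_value
    if (p >= 0.05) n_sig <- n_sig + 1L
  }
  # not significant in at least 90 of 100 seeded shuffles
  expect_gte(n_sig, 90L)
})

test_that("band-wise tonotopy skips thin bands and detects a CD-BF gradient", {
  edges <- 600 * 2^(0:4 / 4)   # four quarter-octave bands
  withr::with_seed(43, {
    bf <- runif(60, 600, 1190)
    cd <- 300 / bf + rnorm(60, 0, 0.02)    # CD ~ 1/BF
    cells <- cellPopulation(
      cell_id = paste0("c", 1:60), bf_hz = bf,
      cp_cycles = wrapPhase(0.2 - cd / 2), cd_ms = cd,
      baseline_hz = 20, amplitude_hz = 50, width_cycles = 0.25)
  })
  tono <- suppressWarnings(bandwiseCdTonotopy(cells, edges))
  expect_equal(nrow(tono$bands), 4L)
  # identical CDs across bands give identical slopes
  flat <- cells
  flat$cd_ms <- rep(c(-0.6, 0.2, 0.6, 1.0), 15)
  flat$cp_cycles <- wrapPhase(0.2 - flat$cd_ms / 2)
  tflat <- suppressWarnings(bandwiseCdTonotopy(flat, edges))
  expect_lt(diff(range(tflat$bands$slope_cycles_per_ms)), 1e-3)
  # a band reduced to 2 cells is skipped with a warning, others survive
  in_band1 <- cells$bf_hz < edges[2]
  thin <- rbind(cells[!in_band1, ], cells[in_band1, ][1:2, ])
  w <- testthat::capture_warnings(tthin <- bandwiseCdTonotopy(thin, edges))
  expect_true(any(grepl("skipped", w)))
  expect_equal(nrow(tthin$bands), 3L)
  expect_error(bandwiseCdTonotopy(cells, 600), "band")
})

test_that("bootstrap SEM of CP/CD is zero without noise, seeded, and shrinks with repetitions", {
  cell <- make_cell(0.15, -0.2, id = "boot")
  quiet <- rateNoiseModel(noise_scale = 0)
  meas0 <- generateExperiment(cell, quiet, n_reps = 3, seed = 8)
  sem0 <- bootstrapCpCdSem(meas0, quiet, bf = 900, n_surrogates = 3,
                           seed = 9)
  # zero up to the sampler's 1e-6 Hz degeneracy floor
  expect_lt(sem0$sem_cp, 1e-4)
  expect_lt(sem0$sem_cd_scaled, 1e-4)

  m <- fix_model
  sem_few <- bootstrapCpCdSem(generateExperiment(cell, m, n_reps = 3,
                                                 seed = 10),
                              m, bf = 900, n_surrogates = 4, seed = 11)
  sem_many <- bootstrapCpCdSem(generateExperiment(cell, m, n_reps = 12,
                                                  seed = 10),
                               m, bf = 900, n_surrogates = 4, seed = 11)
  expect_lt(sem_many$sem_cp, sem_few$sem_cp)
  # determinism under a fixed seed
  sem_rep <- bootstrapCpCdSem(generateExperiment(cell, m, n_reps = 3,
                                                 seed = 10),
                              m, bf = 900, n_surrogates = 4, seed = 11)
  expect_identical(sem_rep$sem_cp, sem_few$sem_cp)
  expect_error(bootstrapCpCdSem(meas0, quiet, bf = 900, n_surrogates = 1),
               "at least 2")
})
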