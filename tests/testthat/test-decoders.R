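# a small decoding testbed shared by the classifier tests
decoder_fixture <- local({
  cells <- generatePopulation(populationGeneratorConfig(n_cells = 30),
                              seed = 9)
  conds <- conditionGrid(fix_geom, n_itd = 21)
  list(cells = cells, conds = conds,
       train = simulatePopulation(cells, fix_model, conds, n_trials = 40,
                                  seed = 1),
       test = simulatePopulation(cells, fix_model, conds, n_trials = 8,
                                 seed = 2))
})

test_that("one-vs-one ensemble separates well-separated noiseless classes exactly", {
  # two tight noiseless clusters at +/-80 us, far apart on a steep code
  cells <- do.call(rbind, lapply(1:10, function(i)
    make_cell(0.25, 0, id = paste0("c", i))))
  class(cells) <- c("cell_population", "data.frame")
  conds <- expand.grid(itd_us = c(-80, -75, 75, 80),
                       frequency_hz = fix_freqs)
  quiet <- rateNoiseModel(noise_scale = 0)
  resp <- simulatePopulation(cells, quiet, conds, n_trials = 6, seed = 92)
  ens <- trainClassifier(resp, n_bins = 2, n_train = 20, seed = 93)
  expect_equal(nrow(ens$pairs), 1L)
  # predictions equal the true bins on the whole noiseless pool, so the
  # only remaining error is the bin-centre discretisation
  pat <- itdcode:::responsePatterns(resp)
  pred <- predictBins(ens, pat$X)
  truth <- findInterval(pat$tau, ens$bin_edges, rightmost.closed = TRUE,
                        all.inside = TRUE)
  expect_equal(pred, truth)
  expect_equal(classifierTestError(ens, resp)$rms_us,
               sqrt(mean((ens$bin_centers[truth] - pat$tau)^2)))
  expect_error(trainClassifier(resp, n_bins = 1, n_train = 5), ">= 2")
  expect_error(trainClassifier(resp, n_bins = 2, n_train = 1e5),
               "n_train")
})

test_that("training error rises and test error falls with the number of training samples", {
  fx <- decoder_fixture
  errs <- t(vapply(c(10, 30, 90, 270), function(nt) {
    ens <- trainClassifier(fx$train, n_bins = 7, n_train = nt, seed = 3)
    c(train = classifierTrainError(ens, fx$train),
      test = classifierTestError(ens, fx$test)$rms_us)
  }, numeric(2)))
  expect_true(all(diff(errs[, "train"]) > 0))
  expect_true(all(diff(errs[, "test"]) < 0))
})

test_that("label-shuffled training yields chance-level test accuracy", {
  fx <- decoder_fixture
  shuffled <- fx$train
  shuffled$conditions$itd_us <- withr::with_seed(
    4, sample(shuffled$conditions$itd_us))
  ens <- trainClassifier(shuffled, n_bins = 7, n_train = 90, seed = 5)
  pat <- itdcode:::responsePatterns(fx$test)
  pred <- predictBins(ens, pat$X)
  truth <- findInterval(pat$tau, ens$bin_edges, rightmost.closed = TRUE,
                        all.inside = TRUE)
  acc <- mean(pred == truth)
  se <- sqrt((1 / 7) * (6 / 7) / length(pred))
  expect_lt(abs(acc - 1 / 7), 3 * se)
})

test_that("classifier test error reports bin-centre RMS with sane bounds", {
  fx <- decoder_fixture
  ens <- trainClassifier(fx$train, n_bins = 7, n_train = 90, seed = 6)
  err <- classifierTestError(ens, fx$test)
  expect_lt(err$rms_us, 2 * fix_geom$tau_max_us)
  expect_equal(sum(err$confusion), err$n_test)
  # noiseless strictly monotone code: error below one bin width
  quiet <- rateNoiseModel(noise_scale = 1e-6)
  mono <- make_cell(0.25, 0, id = "mono")
  conds <- conditionGrid(fix_geom, n_itd = 21, frequencies_hz = 900)
  tr <- simulatePopulation(mono, quiet, conds, n_trials = 30, seed = 7)
  te <- simulatePopulation(mono, quiet, conds, n_trials = 6, seed = 8)
  ens1 <- trainClassifier(tr, n_bins = 5, n_train = 60, seed = 9)
  bin_w <- diff(ens1$bin_edges[1:2])
  expect_lt(classifierTestError(ens1, te)$rms_us, bin_w)
  empty <- te
  empty$rates <- te$rates[, integer(0), , drop = FALSE]
  empty$conditions <- te$conditions[integer(0), ]
  expect_error(classifierTestError(ens1, empty), "empty")
})

test_that("subset acuity reproduces the full population and the trend over sizes", {
  fx <- decoder_fixture
  pr <- itdPrior(fix_geom, 101)
  mi <- vapply(seq_len(nrow(fx$cells)), function(i) {
    mutualInformation(fx$cells[i, ], fix_model, pr, fix_freqs,
                      n_rate = 100)
  }, numeric(1))
  sa <- subsetAcuity(fx$train, fx$test, mi, subset_sizes = c(1, 5, 15, 30),
                     n_bins = 7, n_train = 90, seed = 10)
  full <- trainClassifier(fx$train, 7, 90, seed = 10)
  expect_equal(sa$curve$rms_us[4],
               classifierTestError(full, fx$test)$rms_us)
  # one cell can never beat the full population
  expect_gte(sa$curve$rms_us[1], sa$curve$rms_us[4])
  expect_false(is.na(sa$saturation_size))
  expect_error(subsetAcuity(fx$train, fx$test, mi, subset_sizes = 31,
                            n_bins = 7, n_train = 90), "larger")
})

test_that("difference decoder fits exactly linear data and carries the sign convention", {
  D <- data.frame(itd_us = rep(seq(-100, 100, by = 10), 2),
                  frequency_hz = rep(c(850, 950), each = 21),
                  trial = 1L)
  D$D <- D$itd_us / 4
  dec <- fitDifferenceDecoder(D)
  expect_equal(dec$gain, 4, tolerance = 1e-9)
  expect_equal(dec$intercept, 0, tolerance = 1e-9)
  expect_equal(dec$r_squared, 1, tolerance = 1e-12)
  err <- differenceDecoderError(dec, D)
  expect_lt(err$rms_us, 1e-9)
  expect_error(fitDifferenceDecoder(transform(D, D = 1)), "degenerate")
  # paper-like population: contralateral-leading ITDs raise the
  # contralateral difference signal, so the fitted gain is positive
  cells <- generatePopulation(populationGeneratorConfig(n_cells = 40),
                              seed = 95)
  conds <- conditionGrid(fix_geom, n_itd = 21)
  r1 <- simulatePopulation(cells, fix_model, conds, n_trials = 15,
                           seed = 96)
  r2 <- simulatePopulation(mirrorPopulation(cells), fix_model, conds,
                           n_trials = 15, seed = 97)
  dd <- fitDifferenceDecoder(bilateralDifferenceSignal(r1, r2))
  expect_gt(dd$gain, 0)
  expect_gt(dd$r_squared, 0.9)
})

test_that("difference-code test error is frequency-invariant for the heterogeneous population", {
  cells <- generatePopulation(populationGeneratorConfig(n_cells = 60),
                              seed = 98)
  conds <- conditionGrid(fix_geom, n_itd = 21)
  mir <- mirrorPopulation(cells)
  fit_D <- bilateralDifferenceSignal(
    simulatePopulation(cells, fix_model, conds, n_trials = 15, seed = 99),
    simulatePopulation(mir, fix_model, conds, n_trials = 15, seed = 100))
  dec <- fitDifferenceDecoder(fit_D)
  test_D <- bilateralDifferenceSignal(
    simulatePopulation(cells, fix_model, conds, n_trials = 15, seed = 101),
    simulatePopulation(mir, fix_model, conds, n_trials = 15, seed = 102))
  err <- differenceDecoderError(dec, test_D)
  cv <- stats::sd(err$by_frequency$rms_us) / mean(err$by_frequency$rms_us)
  expect_lt(cv, 0.3)
  expect_gte(err$max_us, err$rms_us)
  expect_error(differenceDecoderError(dec, test_D[integer(0), ]), "empty")
})
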