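# shared fixtures: gerbil-like geometry, fitted-level noise model, the
# 800-1000 Hz stimulus band, and small builders used across test files
fix_geom <- headGeometry()
fix_model <- rateNoiseModel()
fix_freqs <- seq(800, 1000, length.out = 5)

make_cell <- function(cp, cds, bf = 900, baseline = 20, amplitude = 50,
                      width = 0.25, id = "cell") {
  cellPopulation(cell_id = id, bf_hz = bf, cp_cycles = cp,
                 cd_ms = cds / bf * 1e3, baseline_hz = baseline,
                 amplitude_hz = amplitude, width_cycles = width)
}

# noiseless tone-delay samples from known parameters
make_tone_delay <- function(params, n_ipd = 24, span = 1) {
  ipd <- seq(-span / 2, span / 2, length.out = n_ipd)
  list(ipd = ipd, rate = evalCyclicGaussian(params, ipd))
}
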