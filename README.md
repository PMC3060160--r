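# itdcode

Statistical modelling of how populations of auditory brainstem neurons
encode interaural time differences (ITDs) independently of stimulus
frequency.

Neurons in the dorsal nucleus of the lateral lemniscus (DNLL) of the
Mongolian gerbil — one synapse downstream of the binaural coincidence
detectors of the superior olivary complex — fire at rates that depend on
both the ITD of a pure tone and its frequency. The tone delay function of a
cell at frequency *f* is modelled as a cyclic Gaussian of the interaural
phase difference φ = *f*·τ (in cycles):

    r(φ) = b + a · Σ_k exp( −(φ − φ_best + k)² / (2 w²) )

and the best IPD moves linearly with frequency,

    φ_best(f) = CP + CD · f,

which defines each cell's **characteristic phase** (CP, cycles) and
**characteristic delay** (CD, ms), estimated here by circular–linear
regression (slope by mean-resultant-length maximisation, offset by the
cylinder-overlap criterion). Trial-to-trial rate variability follows a
zero-clipped Gaussian whose variance obeys a logarithmic variance–mean law,
σ²(r̄) = v₁ ln(1 + v₂ r̄), Poisson-like at low rates.

On top of this single-cell model the package computes:

* the **mutual information** I(τ; r) between ITD and firing rate,
  marginalised over stimulus frequency, under an ITD prior induced by
  uniformly distributed source angles through the spherical-head
  (Blauert) angle→ITD mapping — including full MI landscapes over the
  (CP, CD·BF) plane and parameter sweeps (head size, stimulus length,
  noise level);
* two population readouts of simulated rate patterns: a **labelled-line
  code** (one-vs-one linear maximum-margin classifiers with majority
  vote over ITD bins) and a **bilateral rate-difference code** (mean
  rate of one hemisphere minus its mirrored counterpart, decoded by a
  linear least-squares ITD estimator);
* a **synthetic-population generator** that emulates the statistical
  structure of the recorded DNLL population (flat BF distribution in the
  800–1000 Hz band, broadly distributed CPs with positive bias, CDs
  peaked at zero and skewed negative, clustering along a
  constant-best-phase line in the CP–CD·BF plane), so that every stage
  is testable without the original recordings.

## Worked example

```r
library(itdcode)

## 1. geometry, noise model, virtual DNLL population
geom  <- headGeometry()                      # gerbil-like: tau_max ~ 112 us
model <- rateNoiseModel()                    # var = 25 ln(1 + 0.2 r), T = 0.2 s
cells <- generatePopulation(populationGeneratorConfig(n_cells = 153), seed = 1)

## 2. population CP-CD structure (circular-linear regression)
st <- populationCpCdStats(cells)

## 3. single-cell mutual information between ITD and rate
prior <- itdPrior(geom, 201)
mi <- mutualInformation(cells[1, ], model, prior,
                        frequencies_hz = seq(800, 1000, length.out = 5))

## 4. the two population readouts
conds <- conditionGrid(geom, n_itd = 41)
train <- simulatePopulation(cells, model, conds, n_trials = 20, seed = 2)
test  <- simulatePopulation(cells, model, conds, n_trials = 8,  seed = 3)
ens   <- trainClassifier(train, n_bins = 10, n_train = 100, seed = 4)

mirror <- mirrorPopulation(cells)
D_fit  <- bilateralDifferenceSignal(
  simulatePopulation(cells,  model, conds, n_trials = 20, seed = 5),
  simulatePopulation(mirror, model, conds, n_trials = 20, seed = 6))
dec    <- fitDifferenceDecoder(D_fit)
D_test <- bilateralDifferenceSignal(
  simulatePopulation(cells,  model, conds, n_trials = 20, seed = 7),
  simulatePopulation(mirror, model, conds, n_trials = 20, seed = 8))
err    <- differenceDecoderError(dec, D_test)
```

This prints (abridged):

```
Cell population: 153 neurons, BF 803-999 Hz
  CP (cycles): median 0.125 [-0.491, 0.477]
  CD (ms):     median 0.084 [-0.496, 0.996]
CP-vs-CD slope: -1.37 ms per cycle (r = 0.73, p = 2.5e-18)
cell synth_001: CP 0.03 cyc, CD 0.04 ms -> MI 0.070 bits
labelled-line RMS acuity: 14.6 us
bilateral difference decoder: R^2 = 0.991, RMS acuity 6.4 us
```

The negative CP-vs-CD slope is the constant-best-phase structure of the
population; the near-midline cell `synth_001` carries little
frequency-invariant ITD information on its own; and the bilateral
difference signal is an almost perfectly linear function of ITD
(R² = 0.991), supporting a two-channel readout with microsecond-scale
acuity. Setting all CPs to zero
(`manipulateCharacteristics(cells, "set_cp_zero")`) collapses the
difference code while barely affecting the labelled-line code — the
central dissociation between the two readout hypotheses.

See the methods vignette (`vignettes/itd-coding.Rmd`) for the model's
assumptions, parameter defaults, and numerical choices.

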