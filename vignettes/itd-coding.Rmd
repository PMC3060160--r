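---
title: "Frequency-invariant ITD coding: model, assumptions, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frequency-invariant ITD coding: model, assumptions, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(itdcode)
```

## The scientific problem

Interaural time differences (ITDs) are the dominant cue for localising
low-frequency sound. Binaural neurons in the gerbil brainstem (here: the
dorsal nucleus of the lateral lemniscus, DNLL, which inherits the ITD
sensitivity of the superior olivary complex) fire at rates that depend
jointly on the ITD and on the tone frequency, so no single neuron's rate
maps one-to-one onto ITD once frequency is allowed to vary. `itdcode`
implements a statistical model of these frequency-dependent tuning curves
and asks two questions: how much frequency-*invariant* ITD information a
single cell carries, and how well two candidate population readouts — a
labelled-line classifier and a bilateral rate-difference (two-channel)
code — recover ITD from simulated population activity.

## Single-cell model

**Tone delay function.** The mean rate at interaural phase difference
φ = f·τ (cycles) is a cyclic Gaussian

$$ r(\varphi) = b + a \sum_{k=-K}^{K}
   \exp\!\left(-\frac{(\varphi - \varphi_{best} + k)^2}{2w^2}\right), $$

with baseline $b \ge 0$ (Hz), amplitude $a \ge 0$ (Hz), width
$w \in [0.02, 1]$ (cycles) and best IPD $\varphi_{best}$. The wrap sum is
truncated at $K = 5$; against a $K = 50$ reference the error stays below
$10^{-6}$ Hz for $w \le 0.5$, the widest tuning we fit in practice
(`test-tuning.R` pins this oracle). Fits are nonlinear least squares on
repetition-averaged rates with eight equally spaced $\varphi_{best}$
starts; ties resolve to the lowest residual, then the lowest best IPD.
The width bounds prevent degenerate spike/flat solutions; a fitted
amplitude below $10^{-3}$ of the mean rate flags the cell as flat
(degenerate) rather than dropping it, leaving the decision downstream.

**Phase–frequency line.** Across the five test frequencies the best IPD
follows $\varphi_{best}(f) = CP + CD \cdot f$. CP (cycles) and CD (ms) come
from circular–linear regression: the slope maximises the mean resultant
length of the circular residuals,
$R_V(m) = |\tfrac1n \sum_j e^{2\pi i (\varphi_j - m x_j)}|$, and the
offset then maximises the mean cosine overlap on the cylinder, whose
maximiser is in closed form the circular mean of the residuals — we use
that closed form rather than a numeric search. The slope search is a
10 µs grid over ±3 ms followed by local refinement; ±3 ms generously
covers the CD range seen in this preparation while staying well below the
aliasing slope set by the ~80–100 Hz frequency spacing (about 10–12 ms),
and a maximiser at the search edge raises an aliasing flag. If the local
refinement does not strictly improve $R_V$ (perfect, machine-flat fits)
the exact grid maximiser is kept, which makes reference cases like a pure
delay line (CP = 0) or a trougher (CP = 0.5) land exactly.

**Rate noise.** Trial rates follow a Gaussian around the tuning mean with
variance $\sigma^2(\bar r) = s\, v_1 \ln(1 + v_2 \bar r)$ ($s$ =
`noise_scale`, default 1), clipped at zero. Defaults: $v_1 = 25$ Hz²,
$v_2 = 0.2$ Hz⁻¹, stimulus duration $T = 0.2$ s, chosen so that
$v_1 v_2 = 1/T$ exactly — at low rates the spike-count variance then
equals the count mean (Poisson-like), while at high rates the variance
grows strongly sublinearly, as the pooled variance–mean data show. The
clipping is implemented as a *renormalised* truncated Gaussian; the
alternative reading (clipped mass as an atom at zero rate) is available
via `clip = "point_mass"`. At the default parameters the two differ
negligibly in every quantity we compute; the renormalised form is the
default because it keeps the conditional density a proper density.

## From angles to ITDs

Source azimuth θ maps to ITD through the spherical-head path-difference
formula $\tau(\theta) = \frac{d}{2c}(\theta + \sin\theta)$, with inter-ear
distance $d = 0.03$ m and $c = 343$ m/s by default, giving a
physiological range of about ±112 µs — a gerbil-like value; both numbers
are config-exposed. The mapping's sensitivity $d\tau/d\theta$ at the
midline is exactly twice its fully-lateral value, so the prior over ITDs
induced by uniformly distributed source angles is densest at the lateral
extremes (edge-to-centre density ratio → 2, no singularity). The prior is
discretised by *bin-integrating* the angle measure — each ITD bin's mass
is the angular measure of its preimage — which is exactly normalised by
construction and avoids committing to a pointwise Jacobian at the range
edges. Inversion is by monotone root-finding at $10^{-9}$ relative
tolerance.

## Mutual information

$I(\tau; r)$ is computed by quadrature on a 201-point ITD grid over the
physiological range and 200 rate bins covering
$[0,\, b + a + 6\sigma_{max}]$. Conditional bin masses are exact Gaussian
CDF differences (not density × width), which keeps the computation stable
down to the deterministic limit; an optional grid-doubling check flags
convergence (default grids converge to well under 0.01 bits). The
conditional distribution at each ITD averages the per-frequency
distributions with uniform weights over the five band frequencies
(a power-law alternative is exposed; at half an octave of bandwidth the
two differ only modestly). Landscape calculations place synthetic cells
with the band-average tuning shape — the element-wise mean of baseline,
amplitude and width, an interpretation we prefer over fitting a curve to
averaged data because it keeps shape and position parameters independent
— at every (CP, CD·BF) grid point, recovering CD as CD·BF divided by the
900 Hz band centre.

Two structural properties follow from the model and are pinned by tests:
the landscape is mirror-symmetric, $I(CP, CD{\cdot}BF) =
I(-CP, -CD{\cdot}BF)$, because the two hemispheres are interchangeable;
and the high-MI ridges run along lines of slope −1 in the
(CP, CD·BF) plane, i.e. lines of constant best phase at the band centre.

## Parameter sweeps and a known limitation

Sweeps over inter-ear distance rebuild the prior at fixed firing
statistics; with growing head size the two mirror ridges merge and the
maximal-MI characteristic phase moves toward zero, so non-zero CPs are
chiefly useful for small heads. Sweeps over stimulus length emulate a
shorter observation window by rescaling the variance law
($v_1 \to v_1 T/T_0$, preserving Poisson consistency $v_1 v_2 = 1/T_0$),
because onset-window tone delay functions are not available to refit.
This emulation captures the overall information loss but, as implemented,
it does *not* move the location of the MI maximum: uniformly scaling the
variance leaves the argmax of the landscape essentially unchanged (we
verified this over four orders of magnitude of noise, both clipping
modes, and count-quantised rate grids). A duration-dependent shift of the
optimal CP would require the onset-specific tuning shapes themselves, so
that effect lies outside what this model can reproduce; the corresponding
assertion in the acceptance tests is deliberately left failing rather
than weakened, and this paragraph is its documentation.

## Population readouts

`simulatePopulation` draws independent trial rates for every cell at
every (ITD × frequency) condition — 41 ITDs across the physiological
range × 5 band frequencies by default. Noise is independent across cells;
the model provides no estimate of interneuronal correlations and we state
that assumption rather than hide it.

**Labelled line.** ITDs are binned into M equal bins; each bin pair gets
a linear soft-margin maximum-margin classifier (libsvm via `e1071`,
cost = 1, features standardised by training statistics — the family is
specified, the hyperparameters are ours and are fixed, not tuned).
Prediction is by majority vote with a deterministic tie-break: summed
signed decision values, then the lower bin index. Acuity is the RMS
difference between predicted bin centre and true ITD on an independently
simulated test set (fresh seeds; default ten times the per-bin training
size). Training error rises and test error falls with training-set size,
and subset analyses rank cells by single-cell MI and report the smallest
subset within 5% of full-population acuity.

**Bilateral difference.** The second hemisphere is the mirrored
population (CP → −CP, CD → −CD); the difference signal D is the mean rate
of one hemisphere minus the other, per condition and trial, and a single
frequency-blind least-squares line τ̂ = gain·D + intercept serves as the
decoder (per-frequency fits are diagnostics only). For the heterogeneous,
constant-best-phase population D is almost perfectly linear in ITD and
the test error is nearly frequency- and ITD-invariant; for a homogeneous
population placed at the single max-MI point the error becomes
frequency-dependent with a minimum at the band centre; and zeroing all
CPs (a delay-line-only, Jeffress-like configuration) destroys the
difference code while changing classifier acuity only by a few percent.
In our generated conditions the CP = 0 manipulation in fact *slightly
degrades* classifier acuity rather than improving it; the corresponding
acceptance assertion is left failing, since the effect's sign plausibly
depends on the exact recorded population, which is not available.

## The synthetic population generator

The generator is the package's stand-in for the unavailable recordings
and defines the study conditions:

* 153 cells, best frequencies uniform in 800–1000 Hz (the best-sampled
  band, where BFs are approximately flat);
* per cell a best phase BP ~ Normal(0.2, 0.1) cycles — the
  constant-best-phase cluster — and a broad, positively biased CP
  (mixture: 50% uniform over the cycle, 50% wrapped Normal(0.2, 0.15));
  then CD·BF = BP − CP plus jitter (0.05 ms), which *constructs* the
  negative circular–linear CP–CD correlation and the zero-peaked,
  negatively skewed CD distribution;
* tuning shapes: baseline 20 ± 8 Hz, amplitude 50 ± 15 Hz, width
  0.25 ± 0.05 cycles, truncated to valid ranges. The broad width reflects
  the smooth, near-sinusoidal tone delay functions of low-frequency
  brainstem neurons and places the model in the regime with the reported
  landscape structure (separated ridges at |BP| ≈ 0.25 for gerbil
  geometry that merge toward CP = 0 for human-like head size); narrower
  widths would instead drive the large-head optimum to the antiphasic
  configuration.

The emulated experiment applies the measurement protocol: 5 frequencies
log-spaced over half an octave around BF, ITDs spanning one full stimulus
cycle per frequency (24 points), at least 3 repetitions, integer spike
counts (rate × duration, rounded). What the generator does **not**
emulate: interneuronal noise correlations, onset/sustained response
differences, non-stationarity across the recording session, and any
tonotopy beyond the sampled band. Tests passing on generated data
therefore validate the pipeline's statistical machinery, not the
biological parameter values themselves.

## Degenerate inputs and numerical conventions

* Phases are reported in (−0.5, 0.5]; positive ITD/IPD means
  contralateral-leading.
* Flat cells: flagged by the tuning fit; their MI is 0 and they
  contribute a constant to population patterns.
* Zero-variance noise (`noise_scale = 0`): the sampler and the binned
  densities use a 1 µHz standard-deviation floor, so "deterministic"
  quantities are reproducible to ~10⁻⁴ Hz.
* Circular–linear fits with all-identical inputs error out; slope
  maximisers at the search boundary are flagged, not silently accepted.
* All stochastic entry points take explicit seeds and restore the RNG
  state (`withr::with_seed`), so identical seeds give identical outputs
  without clobbering the caller's RNG.

## Problem sizes

The shipped tests run the full pipeline at reduced but honest scales
chosen to keep the suite quick: populations of 10–153 cells, 21–41 ITD
points, MI grids of 101–201 × 100–200, a 10⁶-sample Monte-Carlo check of
the MI quadrature, and 41 × 41 landscape grids; the defaults exposed to
users are the larger of these throughout.

## Known limitations

* The duration sweep emulates only the noise consequence of shorter
  windows (see above).
* The Mardia-style circular–linear correlation coefficient loses power
  when the phase–predictor relation wraps more than about one cycle; the
  regression slope itself is unaffected.
* Population decoding assumes independent noise across cells;
  correlated noise would change absolute acuities.
* The generator's parameter values are field-realistic defaults, not
  fits to the (undeposited) recordings.
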