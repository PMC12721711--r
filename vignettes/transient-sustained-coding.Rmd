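---
title: "Quantifying transient and sustained visual coding with LN models and a depressing ribbon-synapse model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying transient and sustained visual coding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(retinaln)
```

## The scientific problem

Parallel retinal pathways split a shared visual input into channels with
different temporal codes: *transient* ganglion cells respond briefly to a
change in light and *sustained* cells report its maintained level. `retinaln`
implements the quantitative machinery used to characterize this split — the
linear–nonlinear (LN) cascade model estimated by reverse correlation,
formula-defined kinetics statistics, paired-flash depression analysis,
excitatory/inhibitory conductance decomposition, and ribbon morphometry
regression — together with a synthetic-data generator whose ground truth is
known, so that every estimator in the package has a parameter-recovery test.

The package's model of the mechanism follows the synaptic hypothesis: both
cell classes receive similar presynaptic (bipolar cell) voltage signals, and
the transient/sustained difference is created at the ribbon synapse by
use-dependent depletion of a readily releasable vesicle pool. Small pools
that replenish slowly transmit change and then fall silent; large, rapidly
replenishing pools sustain transmission.

## The LN model and its estimators

An LN neuron transforms Weber contrast $c(t) = (I(t) - \bar I)/\bar I$ into a
response
$$ r(t) = N\!\left(\sum_{k} f_k\, c(t - k\,\Delta t)\right) + \varepsilon(t), $$
where $f$ is a causal temporal filter and $N$ a monotone static
nonlinearity. Filters are stored *lag-forward* ($f_k$ weights the stimulus
$k\,\Delta t$ seconds before the response); published spike-triggered
averages are usually plotted on a reversed (negative) time axis, which is a
display convention only.

Two estimators are provided:

* **Spike-triggered average** (`compute_sta()`): the mean contrast segment
  preceding each spike. The default implementation computes all lags at once
  by FFT cross-correlation with the binned spike train; a literal
  spike-by-spike averaging path (`method = "direct"`) is kept as the slow
  reference and the two agree to numerical round-off.
* **Spectral deconvolution** (`estimate_linear_filter()`) for continuous
  responses: $\hat F(\omega) = S^*(\omega) R(\omega) / (|S(\omega)|^2 +
  \epsilon)$, inverse-transformed and truncated to the filter length
  (default 0.5 s — measured filters decay well within this span). The
  division is ill-posed wherever the stimulus carries no power, so
  $\epsilon = 10^{-6}\max|S|^2$ and all components above the stimulus
  bandwidth are zeroed before inversion. Consequently the estimate converges
  to the *band-limited* projection of the true kernel; recovery tests
  compare against that projection, which is what any reverse-correlation
  experiment with a band-limited stimulus can know.

The static nonlinearity (`fit_nonlinearity()`) is the binned point-by-point
comparison of the generator signal with the measured response. Bins hold
equal sample counts (20 quantile bins, minimum 50 samples, merged if
smaller) rather than equal widths: with a Gaussian generator signal,
equal-width bins starve the tails. Prediction interpolates linearly between
bin centers and extrapolates as a constant. These choices (bin count,
scheme, regularization) are not dictated by the analysis tradition this
package follows, and all are exposed as arguments.

## Kinetics statistics

`zero_cross_time()` finds the sign change between the first and second lobes
of a filter, sub-sample by linear interpolation. The initial lobe is the
earliest local extremum exceeding `noise_floor_frac` (default 0.1) of the
global peak — the guard exists because estimated filters carry ripple that
would otherwise masquerade as a first lobe. `biphasic_index()` is
$|A|/|B|$: secondary-lobe over initial-lobe magnitude, 0 for monophasic
kernels; for triphasic shapes the dominant opposite-sign excursion after the
zero cross is used. Both statistics are invariant to filter scale and sign.

`step_kinetics()` quantifies step responses by the baseline-subtracted peak
(the peak's sign defines the positive direction, so inward currents need no
special casing), time-to-peak, and the steady-state percentage of peak —
mean over the last 100 ms of a 500-ms step by the electrophysiology
convention, or the last 1 s of a 2-s step for glutamate-sensor imaging
(`steady_window_s = 1`). If a response is still growing at step offset the
percentage can exceed 100 and the summary flags it (`grew_past_peak`).

`paired_flash_ratio()` divides the peak response to the second of two
flashes by the first-flash peak. At a 50-ms interval the two responses
overlap; the second-flash response is isolated by subtracting the
single-flash template, which is exact under linear superposition — a
non-depressing linear system therefore scores exactly 1 at every interval,
making deviations attributable to use dependence. The untangling choice is
not uniquely determined by common practice, so the raw post-onset peak is
available behind `subtract_template = FALSE`.

## The depressing ribbon synapse

The generator's synapse is a single readily releasable pool with occupancy
$p(t) \in [0, P_0]$:
$$ \frac{dp}{dt} = \frac{P_0 - p}{\tau_r} - k\,[d(t) - \theta]_+\, p,
\qquad R(t) = k\,[d(t) - \theta]_+\, p(t), $$
with drive $d(t)$, release rate constant $k$, threshold $\theta$ and
replenishment time constant $\tau_r$. This is the minimal model producing
every effect the analysis measures: transient step responses, paired-flash
depression with recovery $1 - f e^{-\Delta t/\tau_r}$ (per-pulse depletion
fraction $f$), and pool-size-dependent sustainedness. Closed forms used as
oracles: the steady state $R_{ss} = k d' P_0 / (1 + k d' \tau_r)$ with
$d' = d - \theta$, and the impulse-approximation paired-pulse ratio above.
Integration is forward Euler at $\Delta t = 10^{-4}$ s by default; the
per-step decrement is checked and the integrator *errors* (suggesting a
smaller step) rather than silently clamping, and halving the step changes
release traces by well under 1% RMS in the regimes used here. A
reserve-pool cascade, calcium dynamics and multivesicular release are
deliberately out of scope.

## What the synthetic generator emulates — and what it does not

`make_gaussian_noise()` reproduces the photopic noise protocol: Gaussian
intensities with SD 50% of the mean, band-limited 0–60 Hz. The bandwidth is
applied as a frequency-domain brick wall — the protocol names a band, not a
filter shape, and the brick wall is the simplest faithful reading (a
sample-and-hold at a display refresh would add sinc ripple; that variant is
not modeled). Fluctuations are rescaled to the target SD, the mean added,
and negative intensities clipped at zero *without* re-normalizing — a
physical light source saturates; the clipped fraction (≈2.4% at 50%
contrast) is recorded on the object. Clipping re-introduces a small amount
of out-of-band power (order $10^{-5}$ of in-band), which is why spectral
purity is exact only below the clipping regime. The default grid is 1 ms:
stimulus content is ≤ 60 Hz, so acquisition-rate (10 kHz) grids add cost
but no information.

Two frozen presets (`cell_preset()`) emulate the transient ("ont") and
sustained ("ons") pathways:

* receptive-field filters — difference-of-gamma kernels (order 5) whose
  parameters were fixed once by a coarse-to-fine grid search against the
  published kinetics regimes: biphasic index 0.631 / 0.430, zero-cross
  0.0799 / 0.0721 s;
* a rectifying output nonlinearity with threshold at −2 generator units
  (about half a generator SD below the mean drive at 50% contrast), i.e.
  maintained transmission at mean luminance with clipping only in the
  dimming tail. A hard threshold at the mean would discard half the samples
  and inflate reverse-correlation variance far beyond what the measured
  prediction accuracy (r ≈ 0.5–0.6) suggests;
* synapses — ONT: $P_0 = 45$, $k = 90$, $\tau_r = 0.6$ s; ONS:
  $P_0 = 110$, $k = 55$, $\tau_r = 0.1$ s, both with $\theta = 0$, driven
  through a shared, mildly biphasic bipolar filter (DC gain 1). The
  calibration explored nonzero thresholds as an alternative transience
  mechanism but the best fits put the entire ONT/ONS difference in the pool
  parameters, so the thresholds were frozen at zero; $\theta$ remains a
  model knob.

With these numbers the cascade yields steady-state 9.2% vs 45.8% of peak
and paired-flash ratios 0.051 vs 0.288 at 50 ms. The joint target "steady
state ≈ 21% *and* PFR ≈ 0.04" in the transient pathway is unreachable in a
single-pool model — depression deep enough for near-complete paired-flash
suppression necessarily depletes the steady state below ~10% — and the
measurements themselves reflect different preparations (the ≈21%/44%
figures come from 2-s glutamate-imaging steps, while the transient
*currents* decay essentially to baseline). The presets therefore match the
current-recording regime, and every cross-preset ordering (biphasic index,
steady state, paired-flash ratio) holds deterministically or across all
tested seeds.

The generator does **not** emulate: spatial structure (full-field stimuli
only), adaptation beyond vesicle depletion, amacrine circuitry,
correlated/bursty trial noise, spike sorting, or imaging artifacts
(bleaching, movement). Passing recovery tests therefore demonstrate
estimator correctness under the model's assumptions, not robustness to
every pathology of real recordings.

Ribbon morphometry (`make_ribbon_dataset()`) draws per-type lognormal
volumes (type 6 mean 2.5× type 5i, CV 0.45 — chosen to land the realized
median ratio in the published 2–3× range) and vesicle counts linear in
volume (143 000 vesicles/µm³, the inverse of the published volume-per-
vesicle coefficient ≈ 7·10⁻⁶ µm³) plus Gaussian noise variance-matched so
the regression explains ≈ 66% of variance. Counts are rounded and floored
at zero; at the matched noise level the floor binds for ~10% of small-type
ribbons and attenuates the count-on-volume slope by ≈3.5% — visible in the
recovery tests, and a reminder that the regression direction matters: with
noise in the counts, volume-on-count slopes are attenuated by a further
factor of r².

## Conductance decomposition

Currents recorded while clamping at the inhibitory reversal isolate
excitation and vice versa: $g_{exc} = I(E_{inh})/(E_{inh}-E_{exc})$,
$g_{inh} = I(E_{exc})/(E_{exc}-E_{inh})$ (pA/mV → nS). Defaults are
$E_{inh} = -68.5$ mV (the chloride reversal used in the recordings) and
$E_{exc} = 0$ mV (the standard cation-channel assumption; the source
protocol does not state it, so it is an argument, not a constant). No
series-resistance or space-clamp correction is applied. Conductance
excursions below −0.5 nS trigger a warning — the diagnostic for wrong
reversal settings. The peak-conductance ratio takes each conductance's
maximum independently (they need not be simultaneous) and is intended for
trial-averaged traces.

## Numerical and degenerate-input choices

* Filter estimation requires ≥ 10 filter lengths of data and errors on
  (near-)zero in-band stimulus power rather than returning noise.
* `compute_sta()` excludes (and counts) spikes earlier than one window
  length; a single usable spike returns that stimulus segment exactly.
* All-zero filters, zero-variance correlation inputs, constant regression
  predictors, and equal reversal potentials raise immediate errors.
* Zero-cross ties at exactly-zero samples resolve to the sample time;
  sub-sample refinement is linear, so the sine half-period identity is
  exact to machine precision.
* Every stochastic function takes a `seed` and restores the caller's RNG
  state, so library calls never perturb a user's random stream.

## A worked run

```{r run, eval = FALSE}
cfg <- run_config(presets = c("ont", "ons"), seed = 1,
                  n_cells_per_preset = 3, noise_duration_s = 60)
metrics <- run_experiment(cfg, out_dir = "run1")
metrics[, c("preset", "biphasic_index", "steady_state_pct", "pfr_50ms")]
```

Problem sizes used throughout the examples and tests — 60–300 s of noise at
1 kHz for LN fitting, 10-seed preset suites, 20-seed regression suites at
n = 150 ribbons — were chosen so each estimate's sampling error is several
times smaller than the effect it measures, as the recovery tests verify.

## Known limitations

* The depletion model is one pool; phenomena requiring a reserve pool
  (delayed recovery components, facilitation) are out of scope.
* The spectral estimator returns the band-limited kernel; out-of-band
  structure is unidentifiable by design.
* Quantal amplitude and sensor kinetics defaults are order-of-magnitude
  placeholders; no result in the package depends on their absolute values.
* Group statistics across cells (rank tests etc.) are left to standard
  tools; the package emits tidy metric tables for that purpose.
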