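# retinaln

Transient and sustained visual channels leave the retina side by side: some
ganglion cells fire briefly at a change in light, others report its
maintained level. `retinaln` is an R package for quantifying that
difference. It implements the standard analysis chain for temporal coding in
the inner retina — linear–nonlinear (LN) model estimation by reverse
correlation, response-kinetics statistics, paired-flash depression analysis,
excitatory/inhibitory conductance decomposition, and ribbon-morphometry
regression — plus a fully seeded synthetic-data generator (LN model neurons
feeding a depressing ribbon-synapse model) so every estimator ships with a
ground-truth recovery test.

It is intended for cellular/systems neuroscientists analyzing
stimulus–response recordings (patch clamp, spikes, glutamate imaging) and
for anyone who needs a tested reference implementation of these estimators.

## The models

**LN cascade.** A response is modeled as
`r(t) = N( Σ_k f_k · c(t − k·Δt) )` where `c` is Weber contrast,
`f` a causal temporal filter and `N` a monotone static nonlinearity.
The filter is estimated either as a spike-triggered average
(`compute_sta()`, FFT-accelerated with a brute-force reference path) or by
spectral deconvolution of continuous responses
(`estimate_linear_filter()`: cross-spectrum over regularized stimulus power
spectrum, band-limited to where the stimulus has power). The nonlinearity is
fitted by quantile-binning the generator signal against the response
(`fit_nonlinearity()`), and `predict_response()` / `model_performance()`
score held-out predictions.

**Kinetics statistics.** `zero_cross_time()` and `biphasic_index()`
(`|A|/|B|`, secondary over initial filter lobe) summarize filter shape;
`step_kinetics()` computes time-to-peak and steady-state % of peak (mean of
the last 100 ms of a 0.5-s step, or last 1 s of a 2-s imaging step);
`paired_flash_ratio()` quantifies use-dependent depression as the
template-subtracted second-flash peak over the first-flash peak.

**Depressing ribbon synapse.** A single readily releasable pool,
`dp/dt = (P0 − p)/τr − k·[d − θ]₊·p`, release `R = k·[d − θ]₊·p`, with
closed-form steady state `R_ss = k d' P0 / (1 + k d' τr)` and paired-pulse
recovery `1 − f·exp(−Δt/τr)` used as test oracles. Two frozen presets
(`cell_preset("ont")`, `cell_preset("ons")`) emulate the transient and
sustained pathways end to end.

**Conductance decomposition.** `decompose_conductances()` converts currents
clamped at the two reversal potentials (defaults 0 / −68.5 mV) into
`g_exc`/`g_inh` (nS) and `peak_conductance_ratio()` summarizes their
balance.

**Ribbon morphometry.** `make_ribbon_dataset()`, `fit_ribbon_regression()`
and `summarize_groups()` generate and analyze ribbon-volume/vesicle-count
tables (OLS slope, r², per-type quartile summaries).

## Worked example

```r
library(retinaln)

cfg <- run_config(presets = c("ont", "ons"), seed = 1,
                  n_cells_per_preset = 2, noise_duration_s = 60)
metrics <- run_experiment(cfg)
metrics[, c("cell_id", "preset", "zero_cross_s", "biphasic_index",
            "steady_state_pct", "ln_r", "pfr_50ms")]
#>   cell_id preset zero_cross_s biphasic_index steady_state_pct  ln_r pfr_50ms
#> 1  ont_01    ont       0.0801          0.683             9.15 0.990   0.0507
#> 2  ont_02    ont       0.0795          0.617             9.15 0.994   0.0507
#> 3  ons_01    ons       0.0721          0.428            45.78 0.993   0.2884
#> 4  ons_02    ons       0.0722          0.463            45.78 0.992   0.2884
```

Each row is one simulated cell: a noise stimulus is generated, the cell's
noisy LN response fitted, the fitted filter's kinetics measured, the model
scored on held-out repeated noise (`ln_r`), and the cell's synaptic cascade
run through the contrast-step and paired-flash protocols. The transient
(`ont`) cells show more biphasic filters with later zero crossings, small
steady-state percentages and near-complete paired-flash suppression at
50 ms; the sustained (`ons`) cells the opposite — the directional signature
the analysis is built to detect. With `out_dir = ...`, the run also writes
`metrics.csv`, per-cell model JSONs and a manifest with config, versions and
file hashes; identical configs reproduce the table byte-for-byte.

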