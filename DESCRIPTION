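Package: retinaln
Title: Linear-Nonlinear Model Estimation and Ribbon-Synapse Depression
    Analysis for Retinal Neural Coding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying transient versus sustained visual coding in
    the inner retina. Generates band-limited Gaussian noise, contrast-step and
    paired-flash light stimuli; simulates linear-nonlinear (LN) model neurons,
    inhomogeneous Poisson spike trains, and a depressing ribbon-synapse model
    (readily releasable vesicle pool with use-dependent depletion and
    first-order replenishment) through to excitatory postsynaptic currents and
    glutamate-sensor fluorescence; estimates temporal linear filters by
    reverse correlation (spike-triggered averaging and spectral
    deconvolution) and fits static nonlinearities by quantile binning;
    computes response-kinetics statistics (zero-cross time, biphasic index,
    time to peak, steady-state percentage of peak, paired-flash ratio);
    decomposes voltage-clamp currents into excitatory and inhibitory
    conductances; and fits ribbon-morphometry regressions relating ribbon
    volume to tethered vesicle counts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
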