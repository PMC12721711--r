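# Frozen synthetic-cell presets emulating the two alpha ganglion-cell
# pathways: "ont" (ON transient) and "ons" (ON sustained). All numbers were
# fixed once by a coarse-to-fine grid-search calibration against the
# published kinetics regimes (see the methods vignette) and are referenced
# by tests and pipelines by name, never re-derived at run time.

.preset_table <- list(
  ont = list(
    label = "ON-T-like (transient)",
    # receptive-field filter emulating measured transient STAs:
    # biphasic index ~0.63, zero cross ~0.080 s
    filter = list(peak_amp = 1, trough_amp = 0.77,
                  tau_rise_s = 0.01175, tau_damp_s = 0.01610),
    # rectifying output with threshold half a generator SD below the mean
    # drive: maintained release at mean luminance, clipped in the dimming tail
    nl_threshold = -2, nl_gain = 1,
    # small, slowly replenishing releasable pool -> strong paired-flash
    # depression and a transient step response
    synapse = list(pool_size_P0 = 45, release_rate_k = 90,
                   drive_threshold_theta = 0, replenish_tau_s = 0.6)
  ),
  ons = list(
    label = "ON-S-like (sustained)",
    # biphasic index ~0.43, zero cross ~0.072 s
    filter = list(peak_amp = 1, trough_amp = 0.75,
                  tau_rise_s = 0.01025, tau_damp_s = 0.01275),
    nl_threshold = -2, nl_gain = 1,
    # larger, fast-replenishing pool -> sustained transmission, weak
    # paired-flash depression
    synapse = list(pool_size_P0 = 110, release_rate_k = 55,
                   drive_threshold_theta = 0, replenish_tau_s = 0.1)
  )
)

# Shared presynaptic drive: both pathways are fed by bipolar cells whose
# voltage responses are similar (mildly biphasic, partially sustained); the
# kinetic difference is made at the synapse. DC gain is normalized to 1 so a
# contrast step of c settles at drive c.
.bipolar_drive_filter <- function(dt_s) {
  f <- make_ground_truth_filter(1, 0.45, 0.02, 0.032, dt_s, 0.5)
  f$taps <- f$taps / sum(f$taps)
  f
}

#' Synthetic cell presets
#'
#' Returns the frozen parameter set for one of the two model cells:
#' `"ont"`, an ON-transient-like cell (strongly biphasic receptive-field
#' filter; small, slowly replenishing vesicle pool that depresses deeply),
#' or `"ons"`, an ON-sustained-like cell (less biphasic filter; large,
#' rapidly replenishing pool that sustains release).
#'
#' @param name `"ont"` or `"ons"`.
#' @param dt_s Sample interval at which concrete model objects are built
#'   (default `1e-4` s, fine enough for stable synapse integration).
#' @return A list of class `cell_preset` with elements `name`, `label`,
#'   `dt_s`, `filter` (the cell's [linear_filter()]), `ln`
#'   (a [ground_truth_ln()] using that filter and a rectifying output),
#'   `synapse` (a [depressing_synapse()]), and `bipolar_filter` (the shared
#'   presynaptic drive filter, DC gain 1).
#' @export
cell_preset <- function(name = c("ont", "ons"), dt_s = 1e-4) {
  name <- match.arg(name)
  check_scalar(dt_s, "dt_s", positive = TRUE)
  p <- .preset_table[[name]]
  filt <- make_ground_truth_filter(p$filter$peak_amp, p$filter$trough_amp,
                                   p$filter$tau_rise_s, p$filter$tau_damp_s,
                                   dt_s, 0.5)
  structure(list(
    name = name, label = p$label, dt_s = dt_s,
    filter = filt,
    ln = ground_truth_ln(filt, rectifier_nl(p$nl_threshold, p$nl_gain), "pA"),
    synapse = do.call(depressing_synapse, p$synapse),
    bipolar_filter = .bipolar_drive_filter(dt_s)
  ), class = "cell_preset")
}

#' @export
print.cell_preset <- function(x, ...) {
  cat(sprintf("<cell_preset> %s\n", x$label))
  print(x$synapse)
  invisible(x)
}

# Drive a preset's ribbon synapse with a stimulus: bipolar generator signal
# -> pool depletion -> release -> EPSC.
preset_epsc <- function(preset, stim, noise_sd = 0, seed = NULL) {
  drive <- as.numeric(generator_signal(preset$bipolar_filter, stim))
  rel <- simulate_depressing_release(drive, stim$dt_s, preset$synapse)
  simulate_epsc(rel$release_rate, stim$dt_s, noise_sd = noise_sd, seed = seed)
}

#' Simulate a preset cell's step-evoked excitatory current
#'
#' Runs a contrast step through the preset's presynaptic cascade (bipolar
#' drive filter, depressing ribbon synapse, quantal EPSC kernel) and returns
#' the current plus its step kinetics.
#'
#' @param preset A [cell_preset()].
#' @param contrast Step Weber contrast (default 0.5).
#' @param step_dur_s Step duration (s), default 0.5.
#' @param noise_sd Current noise SD (pA), default 0.
#' @param seed Optional seed for the noise.
#' @return List with `current` (pA), `dt_s`, `step_onset_s`, `step_dur_s`,
#'   and `kinetics` (a [step_kinetics()] summary using the
#'   last-100-ms steady-state window).
#' @export
preset_step_response <- function(preset, contrast = 0.5, step_dur_s = 0.5,
                                 noise_sd = 0, seed = NULL) {
  stopifnot(inherits(preset, "cell_preset"))
  onset <- 0.5
  stim <- make_step(100, contrast, onset, step_dur_s,
                    total_dur_s = onset + step_dur_s + 0.5, dt_s = preset$dt_s)
  cur <- preset_epsc(preset, stim, noise_sd = noise_sd, seed = seed)
  list(current = cur, dt_s = preset$dt_s, step_onset_s = onset,
       step_dur_s = step_dur_s,
       kinetics = step_kinetics(cur, preset$dt_s, onset, step_dur_s,
                                steady_window_s = 0.1,
                                baseline_window_s = 0.1))
}

#' Simulate a preset cell's paired-flash experiment
#'
#' Runs the paired-flash protocol (two 400%-contrast, 10-ms flashes at each
#' inter-flash interval, plus the single-flash template) through the
#' preset's synaptic cascade and computes the paired-flash ratios by
#' template subtraction.
#'
#' @param preset A [cell_preset()].
#' @param intervals_s Onset-to-onset intervals (s), default
#'   `c(0.05, 0.1, 0.2, 0.4)`.
#' @param noise_sd Current noise SD (pA), default 0.
#' @param seed Optional seed.
#' @return A [paired_flash_ratio()] result.
#' @export
preset_paired_flash <- function(preset, intervals_s = c(0.05, 0.1, 0.2, 0.4),
                                noise_sd = 0, seed = NULL) {
  stopifnot(inherits(preset, "cell_preset"))
  pf <- make_paired_flash(100, flash_contrast = 4, flash_dur_s = 0.01,
                          intervals_s = intervals_s, dt_s = preset$dt_s,
                          pre_s = 0.3, post_s = 0.6)
  single <- preset_epsc(preset, pf$single, noise_sd = noise_sd, seed = seed)
  paired <- lapply(seq_along(pf$paired), function(j) {
    sd_j <- if (is.null(seed)) NULL else seed + j
    preset_epsc(preset, pf$paired[[j]], noise_sd = noise_sd, seed = sd_j)
  })
  names(paired) <- names(pf$paired)
  paired_flash_ratio(paired, single, preset$dt_s, pf$first_onset_s,
                     intervals_s = intervals_s, window_s = 0.3)
}
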