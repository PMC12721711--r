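# Formula-defined response-kinetics statistics: zero-cross time and biphasic
# index of temporal filters, step-response kinetics, and the paired-flash
# ratio that quantifies use-dependent synaptic depression.

# Local extrema (interior sign changes of the first difference) of a filter.
local_extrema <- function(x) {
  d <- diff(x)
  s <- sign(d)
  nz <- which(s != 0)
  if (length(nz) < 2) return(integer(0))
  idx <- integer(0)
  for (j in seq_len(length(nz) - 1L)) {
    if (s[nz[j]] != s[nz[j + 1L]]) idx <- c(idx, nz[j] + 1L)
  }
  idx
}

# Initial lobe extremum: earliest local extremum whose magnitude clears the
# noise floor. Falls back to the global |max| when the waveform is monotone
# over its span (e.g. a truncated monophasic kernel).
initial_lobe_index <- function(taps, noise_floor_frac) {
  floor_amp <- noise_floor_frac * max(abs(taps))
  ext <- local_extrema(taps)
  ext <- ext[abs(taps[ext]) >= floor_amp]
  if (length(ext) == 0) which.max(abs(taps)) else ext[1L]
}

#' Zero-cross time of a biphasic filter
#'
#' Finds the initial lobe of the filter (the earliest local extremum whose
#' magnitude exceeds `noise_floor_frac` of the global peak, guarding against
#' ripple in estimated filters) and returns the time at which the waveform
#' first changes sign after that extremum, refined to sub-sample precision
#' by linear interpolation. Returns `NA` for monophasic filters with no sign
#' change. Reported on the causal lag axis; on the conventional reversed STA
#' time axis the same crossing appears at the negated lag.
#'
#' @param filter A [linear_filter()].
#' @param noise_floor_frac Fraction of the global peak magnitude below which
#'   extrema are treated as noise (default 0.1).
#' @return Zero-cross time in seconds, or `NA_real_` if none.
#' @export
zero_cross_time <- function(filter, noise_floor_frac = 0.1) {
  stopifnot(inherits(filter, "linear_filter"))
  check_scalar(noise_floor_frac, "noise_floor_frac", nonneg = TRUE)
  taps <- filter$taps
  if (all(taps == 0)) stop("degenerate input: all-zero filter", call. = FALSE)
  i0 <- initial_lobe_index(taps, noise_floor_frac)
  if (i0 >= length(taps)) return(NA_real_)
  s <- sign(taps[i0])
  for (k in seq(i0 + 1L, length(taps))) {
    if (taps[k] * s < 0) {
      y1 <- taps[k - 1L]
      y2 <- taps[k]
      # lag of sample j is (j - 1) * dt; interpolate between k-1 and k
      return(((k - 2L) + y1 / (y1 - y2)) * filter$dt_s)
    }
    if (taps[k] == 0 && k < length(taps) && taps[k + 1L] * s < 0) {
      return((k - 1L) * filter$dt_s)
    }
  }
  NA_real_
}

#' Biphasic index of a filter
#'
#' Ratio `|A| / |B|` where `|B|` is the absolute peak amplitude of the
#' initial lobe and `|A|` the largest opposite-sign amplitude after the zero
#' crossing (for triphasic filters this picks the dominant secondary lobe).
#' Monophasic filters return 0. The index is invariant to overall scaling
#' and to sign flips of the filter.
#'
#' @inheritParams zero_cross_time
#' @return Dimensionless index `>= 0`.
#' @export
biphasic_index <- function(filter, noise_floor_frac = 0.1) {
  stopifnot(inherits(filter, "linear_filter"))
  taps <- filter$taps
  if (all(taps == 0)) stop("degenerate input: all-zero filter", call. = FALSE)
  i0 <- initial_lobe_index(taps, noise_floor_frac)
  B <- abs(taps[i0])
  zc <- zero_cross_time(filter, noise_floor_frac)
  if (is.na(zc)) return(0)
  k0 <- floor(zc / filter$dt_s) + 2L   # first sample index after the crossing
  if (k0 > length(taps)) return(0)
  seg <- taps[k0:length(taps)] * (-sign(taps[i0]))
  A <- max(seg, 0)
  A / B
}

#' Step-response kinetics
#'
#' Quantifies how transient or sustained a step-evoked response is. The
#' baseline (mean over `baseline_window_s` before onset) is subtracted; the
#' peak is the largest-magnitude excursion within the step, whose sign
#' defines the positive direction; `time_to_peak_s` is measured from step
#' onset to the end of the sample containing the peak; and
#' `steady_state_pct` is 100 times the mean response over the last
#' `steady_window_s` of the step divided by the peak. Low percentages mean
#' transient responses, values near 100 sustained ones; values above 100
#' (response still growing at step offset) are flagged via the
#' `grew_past_peak` field.
#'
#' The default windows follow the electrophysiology convention (steady state
#' over the last 100 ms of a 500-ms step); for 2-s glutamate-imaging steps
#' use `steady_window_s = 1`.
#'
#' @param response Numeric response vector.
#' @param dt_s Sample interval (s).
#' @param step_onset_s,step_dur_s Step onset time and duration (s).
#' @param steady_window_s Steady-state window at the end of the step (s),
#'   default 0.1.
#' @param baseline_window_s Baseline window before onset (s), default 0.1.
#' @return A list of class `kinetics_summary`: `time_to_peak_s`, `peak_amp`
#'   (baseline-subtracted, in the peak's positive direction),
#'   `steady_state_amp`, `steady_state_pct`, `baseline`, `peak_sign`,
#'   `grew_past_peak`.
#' @export
step_kinetics <- function(response, dt_s, step_onset_s, step_dur_s = 0.5,
                          steady_window_s = 0.1, baseline_window_s = 0.1) {
  response <- as.numeric(response)
  check_numeric_vector(response, "response", min_len = 4L)
  check_scalar(dt_s, "dt_s", positive = TRUE)
  check_scalar(step_onset_s, "step_onset_s", nonneg = TRUE)
  check_scalar(step_dur_s, "step_dur_s", positive = TRUE)
  check_scalar(steady_window_s, "steady_window_s", positive = TRUE)
  check_scalar(baseline_window_s, "baseline_window_s", positive = TRUE)
  if (steady_window_s > step_dur_s) {
    stop_param("steady_window_s", "cannot exceed the step duration")
  }

  n <- length(response)
  i_on <- round(step_onset_s / dt_s) + 1L
  n_step <- round(step_dur_s / dt_s)
  i_off <- i_on + n_step - 1L
  i_base0 <- i_on - round(baseline_window_s / dt_s)
  if (i_base0 < 1L || i_off > n) {
    stop_param("step_onset_s", "baseline/step windows must lie inside the trace")
  }

  baseline <- mean(response[i_base0:(i_on - 1L)])
  y <- response - baseline

  step_seg <- y[i_on:i_off]
  ipk <- which.max(abs(step_seg))
  pk_sign <- sign(step_seg[ipk])
  if (pk_sign == 0) pk_sign <- 1
  peak <- pk_sign * step_seg[ipk]
  time_to_peak <- ipk * dt_s

  n_ss <- round(steady_window_s / dt_s)
  ss <- mean(pk_sign * step_seg[(n_step - n_ss + 1L):n_step])
  structure(list(time_to_peak_s = time_to_peak,
                 peak_amp = peak,
                 steady_state_amp = ss,
                 steady_state_pct = 100 * ss / peak,
                 baseline = baseline,
                 peak_sign = pk_sign,
                 grew_past_peak = ss > peak),
            class = "kinetics_summary")
}

#' @export
print.kinetics_summary <- function(x, ...) {
  cat(sprintf(
    "<kinetics_summary> time to peak %.4g s, peak %.4g, steady state %.1f%% of peak\n",
    x$time_to_peak_s, x$peak_amp, x$steady_state_pct))
  invisible(x)
}

#' Paired-flash ratio
#'
#' Quantifies use-dependent depression as the peak amplitude of the response
#' to the second of two flashes divided by the peak response to the first.
#' The first-flash peak is measured from the single-flash template; the
#' second-flash response is isolated by subtracting the template from each
#' paired trace (exact under linear superposition, so a non-depressing
#' linear system scores 1 at every interval), and its peak is taken within
#' `window_s` after the second-flash onset. Set
#' `subtract_template = FALSE` to take the raw post-onset peak instead.
#'
#' @param paired_responses Named list of numeric response traces, one per
#'   inter-flash interval; names are the intervals in seconds (as produced
#'   with the stimuli from [make_paired_flash()]).
#' @param single_flash_response Numeric template trace: the response to the
#'   first flash alone, same conditions and length.
#' @param dt_s Sample interval (s).
#' @param first_onset_s Onset time of the first flash (s).
#' @param intervals_s Inter-flash (onset-to-onset) intervals in seconds;
#'   defaults to the names of `paired_responses`.
#' @param window_s Peak-search window after each flash onset (s), default
#'   0.3.
#' @param baseline_window_s Baseline window before the first flash (s),
#'   default 0.1; the baseline is subtracted from every trace.
#' @param subtract_template Isolate the second-flash response by template
#'   subtraction (default `TRUE`).
#' @return A list of class `paired_flash_result`: `intervals_s`, `ratios`
#'   (one per interval), `first_peak_amp`.
#' @export
paired_flash_ratio <- function(paired_responses, single_flash_response, dt_s,
                               first_onset_s,
                               intervals_s = as.numeric(names(paired_responses)),
                               window_s = 0.3, baseline_window_s = 0.1,
                               subtract_template = TRUE) {
  if (!is.list(paired_responses) || length(paired_responses) == 0) {
    stop_param("paired_responses", "must be a non-empty list of traces")
  }
  check_numeric_vector(intervals_s, "intervals_s")
  if (length(intervals_s) != length(paired_responses)) {
    stop_param("intervals_s", "must provide one interval per paired trace")
  }
  template <- as.numeric(single_flash_response)
  check_numeric_vector(template, "single_flash_response", min_len = 4L)
  check_scalar(dt_s, "dt_s", positive = TRUE)
  check_scalar(first_onset_s, "first_onset_s", nonneg = TRUE)
  check_scalar(window_s, "window_s", positive = TRUE)

  i_on1 <- round(first_onset_s / dt_s) + 1L
  n_win <- round(window_s / dt_s)
  n_base <- round(baseline_window_s / dt_s)
  if (i_on1 - n_base < 1L) stop_param("baseline_window_s", "precedes the trace start")
  base_idx <- (i_on1 - n_base):(i_on1 - 1L)

  template <- template - mean(template[base_idx])
  w1 <- i_on1:min(i_on1 + n_win - 1L, length(template))
  i_pk1 <- w1[which.max(abs(template[w1]))]
  pk_sign <- sign(template[i_pk1])
  if (pk_sign == 0) pk_sign <- 1
  first_peak <- pk_sign * template[i_pk1]
  if (first_peak <= 0) {
    stop("degenerate template: no first-flash response found", call. = FALSE)
  }

  ratios <- vapply(seq_along(paired_responses), function(j) {
    tr <- as.numeric(paired_responses[[j]])
    if (length(tr) != length(template)) {
      stop_param("paired_responses", "trace length differs from the template")
    }
    tr <- tr - mean(tr[base_idx])
    i_on2 <- i_on1 + round(intervals_s[j] / dt_s)
    w2 <- i_on2:(i_on2 + n_win - 1L)
    if (max(w2) > length(tr)) {
      stop_param("window_s", "second-flash analysis window exceeds the trace")
    }
    resid <- if (subtract_template) tr - template else tr
    max(pk_sign * resid[w2]) / first_peak
  }, numeric(1))

  structure(list(intervals_s = intervals_s, ratios = ratios,
                 first_peak_amp = first_peak),
            class = "paired_flash_result")
}

#' @export
print.paired_flash_result <- function(x, ...) {
  cat("<paired_flash_result>\n")
  for (j in seq_along(x$intervals_s)) {
    cat(sprintf("  interval %5.0f ms : ratio %.3f\n",
                1000 * x$intervals_s[j], x$ratios[j]))
  }
  invisible(x)
}
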