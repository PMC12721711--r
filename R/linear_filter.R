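#' Causal temporal linear filter
#'
#' A `linear_filter` holds kernel weights on a causal lag axis: `taps[k]`
#' weights the stimulus contrast `(k - 1) * dt_s` seconds before the response
#' sample. This lag-forward convention is used for all computation; published
#' spike-triggered averages are conventionally plotted with the time axis
#' reversed (negative times), which only affects display, not analysis.
#'
#' @param taps Numeric vector of kernel weights (per-sample contrast
#'   weights), length `>= 2`, finite.
#' @param dt_s Sample interval in seconds.
#' @return An object of class `linear_filter` with elements `taps`, `dt_s`.
#' @seealso [lag_axis()], [make_ground_truth_filter()],
#'   [estimate_linear_filter()], [compute_sta()]
#' @export
linear_filter <- function(taps, dt_s) {
  check_numeric_vector(taps, "taps", min_len = 2L)
  check_scalar(dt_s, "dt_s", positive = TRUE)
  structure(list(taps = as.numeric(taps), dt_s = dt_s),
            class = "linear_filter")
}

#' @export
print.linear_filter <- function(x, ...) {
  cat(sprintf("<linear_filter> %d taps, dt = %g s (span %.3g s)\n",
              length(x$taps), x$dt_s, length(x$taps) * x$dt_s))
  invisible(x)
}

#' Lag axis of a filter
#'
#' @param filter A [linear_filter()].
#' @return Numeric vector of lags in seconds (`0, dt, 2 dt, ...`).
#' @export
lag_axis <- function(filter) {
  stopifnot(inherits(filter, "linear_filter"))
  (seq_along(filter$taps) - 1) * filter$dt_s
}

# Unit-peak gamma bump of a given order: g(t) peaks at 1 when t = order * tau.
gamma_bump <- function(t, tau, order) {
  u <- t / tau
  ifelse(t <= 0, 0, (u / order)^order * exp(order - u))
}

#' Parametric biphasic ground-truth kernel (difference of gammas)
#'
#' Constructs a causal kernel as the difference of two unit-peak gamma bumps
#' of fixed order 5: a fast positive lobe (ON convention) with time constant
#' `tau_rise_s` minus a slower opposing lobe with time constant `tau_damp_s`.
#' The lobe weights and time constants control the biphasic index and
#' zero-cross time analytically enough that preset shapes emulating measured
#' transient and sustained receptive-field filters can be frozen by a
#' fine-grid calibration (see [cell_preset()]).
#'
#' @param peak_amp Weight of the initial (positive) lobe, `>= 0`.
#' @param trough_amp Weight of the opposing lobe, `>= 0`; 0 gives a
#'   monophasic kernel.
#' @param tau_rise_s Time constant of the initial lobe (s); the lobe peaks
#'   near `5 * tau_rise_s`.
#' @param tau_damp_s Time constant of the opposing lobe (s); must exceed
#'   `tau_rise_s` so the second lobe follows the first.
#' @param dt_s Sample interval (s).
#' @param T_filt_s Kernel span (s); must be long enough to contain both
#'   lobes (`>= 5 * tau_damp_s`).
#' @return A [linear_filter()].
#' @export
make_ground_truth_filter <- function(peak_amp = 1, trough_amp = 0.5,
                                     tau_rise_s = 0.02, tau_damp_s = 0.032,
                                     dt_s = 1e-3, T_filt_s = 0.5) {
  check_scalar(peak_amp, "peak_amp", nonneg = TRUE)
  check_scalar(trough_amp, "trough_amp", nonneg = TRUE)
  check_scalar(tau_rise_s, "tau_rise_s", positive = TRUE)
  check_scalar(tau_damp_s, "tau_damp_s", positive = TRUE)
  check_scalar(dt_s, "dt_s", positive = TRUE)
  check_scalar(T_filt_s, "T_filt_s", positive = TRUE)
  if (tau_damp_s <= tau_rise_s) {
    stop_param("tau_damp_s", "must exceed tau_rise_s (second lobe follows the first)")
  }
  order <- 5
  if (T_filt_s < order * tau_damp_s) {
    stop_param("T_filt_s",
               sprintf("too short to contain both lobes; need >= %g s",
                       order * tau_damp_s))
  }
  t <- seq(0, T_filt_s - dt_s, by = dt_s)
  taps <- peak_amp * gamma_bump(t, tau_rise_s, order) -
    trough_amp * gamma_bump(t, tau_damp_s, order)
  linear_filter(taps, dt_s)
}

#' Convolve a filter with a stimulus (generator signal)
#'
#' Causal discrete convolution of a linear filter with the Weber contrast of
#' a stimulus: the linear stage of the LN cascade, often called the generator
#' signal. The first `length(taps)` samples are a burn-in during which the
#' convolution has not yet seen a full filter length of stimulus; their count
#' is attached as attribute `burn_in`.
#'
#' @param filter A [linear_filter()].
#' @param stim A [stimulus_trace()] with matching `dt_s`.
#' @return Numeric vector the length of the stimulus, with attribute
#'   `burn_in` (number of initial samples to discard before fitting).
#' @export
generator_signal <- function(filter, stim) {
  stopifnot(inherits(filter, "linear_filter"), inherits(stim, "stimulus_trace"))
  if (!isTRUE(all.equal(filter$dt_s, stim$dt_s))) {
    stop_param("stim", "sample interval does not match the filter's dt_s")
  }
  g <- fft_causal_conv(contrast(stim), filter$taps)
  attr(g, "burn_in") <- length(filter$taps)
  g
}

drop_burn_in <- function(x, burn_in = attr(x, "burn_in")) {
  if (is.null(burn_in) || burn_in <= 0) return(as.numeric(x))
  as.numeric(x[-seq_len(burn_in)])
}
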