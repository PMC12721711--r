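#' Light-stimulus trace
#'
#' A `stimulus_trace` is a regularly sampled light-intensity time series in
#' arbitrary photoisomerization-rate units. Intensities are never negative;
#' the Weber contrast convention `(I - I_mean) / I_mean` relative to the
#' stored `mean_level` is used throughout the package.
#'
#' @param values Numeric vector of intensity samples (all `>= 0`).
#' @param dt_s Sample interval in seconds.
#' @param mean_level Mean (adapting) intensity the contrast convention is
#'   anchored to. Defaults to `mean(values)`.
#' @param bandwidth_hz Optional stimulus bandwidth in Hz (recorded for noise
#'   stimuli; analysis routines use it to restrict spectral operations to the
#'   band where the stimulus has power).
#' @return An object of class `stimulus_trace`: a list with elements
#'   `values`, `dt_s`, `mean_level`, `bandwidth_hz` plus generation metadata.
#' @seealso [make_gaussian_noise()], [make_step()], [make_paired_flash()],
#'   [contrast()]
#' @export
stimulus_trace <- function(values, dt_s, mean_level = mean(values),
                           bandwidth_hz = NULL) {
  check_numeric_vector(values, "values", min_len = 2L)
  check_scalar(dt_s, "dt_s", positive = TRUE)
  check_scalar(mean_level, "mean_level", positive = TRUE)
  if (any(values < 0)) stop_param("values", "light intensity cannot be negative")
  if (!is.null(bandwidth_hz)) check_scalar(bandwidth_hz, "bandwidth_hz", positive = TRUE)
  structure(
    list(values = as.numeric(values), dt_s = dt_s, mean_level = mean_level,
         bandwidth_hz = bandwidth_hz, seed = NULL, clipped_frac = 0),
    class = "stimulus_trace"
  )
}

#' @export
print.stimulus_trace <- function(x, ...) {
  dur <- length(x$values) * x$dt_s
  cat(sprintf(
    "<stimulus_trace> %d samples, dt = %g s (%.3g s), mean level = %g\n",
    length(x$values), x$dt_s, dur, x$mean_level))
  if (!is.null(x$bandwidth_hz)) {
    cat(sprintf("  bandwidth %g Hz, realized contrast SD %.4f, clipped %.2f%%\n",
                x$bandwidth_hz, stats::sd(contrast(x)), 100 * x$clipped_frac))
  }
  invisible(x)
}

#' Weber contrast of a stimulus trace
#'
#' @param stim A [stimulus_trace()].
#' @return Numeric vector `(values - mean_level) / mean_level`.
#' @export
contrast <- function(stim) {
  stopifnot(inherits(stim, "stimulus_trace"))
  (stim$values - stim$mean_level) / stim$mean_level
}

#' Band-limited Gaussian noise stimulus
#'
#' Draws white Gaussian samples on the `dt_s` grid, applies an ideal
#' (frequency-domain brick-wall) low-pass at `bandwidth_hz`, rescales the
#' fluctuation to the requested contrast standard deviation, adds the mean
#' level, and clips at zero intensity. The clipped fraction is recorded in
#' the returned object (`$clipped_frac`); the trace is not re-normalized
#' after clipping, mimicking a physical light source that saturates at zero.
#'
#' The defaults reproduce the photopic noise protocol used for receptive
#' field estimation in the retina: contrast SD 50% of the mean and 0-60 Hz
#' bandwidth.
#'
#' @param mean_level Mean intensity (arbitrary units, `> 0`).
#' @param contrast_sd Fluctuation SD as a fraction of the mean, in `(0, 1]`
#'   (0 is accepted and yields a constant trace).
#' @param bandwidth_hz Low-pass cut-off in Hz; must not exceed the Nyquist
#'   frequency `1 / (2 * dt_s)`.
#' @param duration_s Trace duration in seconds.
#' @param dt_s Sample interval in seconds (default 1 ms).
#' @param seed Optional integer seed; fixed seeds give bit-identical traces.
#' @return A [stimulus_trace()] with `bandwidth_hz` and `seed` recorded.
#' @examples
#' stim <- make_gaussian_noise(100, 0.5, 60, duration_s = 10, seed = 1)
#' sd(contrast(stim))  # close to 0.5
#' @export
make_gaussian_noise <- function(mean_level, contrast_sd = 0.5,
                                bandwidth_hz = 60, duration_s,
                                dt_s = 1e-3, seed = NULL) {
  check_scalar(mean_level, "mean_level", positive = TRUE)
  check_scalar(contrast_sd, "contrast_sd", nonneg = TRUE)
  if (contrast_sd > 1) stop_param("contrast_sd", "must be in [0, 1]")
  check_scalar(duration_s, "duration_s", positive = TRUE)
  check_scalar(dt_s, "dt_s", positive = TRUE)
  check_scalar(bandwidth_hz, "bandwidth_hz", positive = TRUE)
  nyquist <- 1 / (2 * dt_s)
  if (bandwidth_hz > nyquist) {
    stop_param("bandwidth_hz",
               sprintf("exceeds the Nyquist frequency %g Hz", nyquist))
  }
  n <- round(duration_s / dt_s)
  if (n < 2) stop_param("duration_s", "must cover at least 2 samples")

  if (contrast_sd == 0) {
    return(stimulus_trace(rep(mean_level, n), dt_s, mean_level, bandwidth_hz))
  }

  x <- with_local_seed(seed, stats::rnorm(n))
  x <- bandlimit(x, dt_s, bandwidth_hz)
  x <- x - mean(x)
  x <- x * (contrast_sd / stats::sd(x))
  values <- mean_level * (1 + x)
  clipped <- values < 0
  values[clipped] <- 0

  out <- stimulus_trace(values, dt_s, mean_level, bandwidth_hz)
  out$seed <- seed
  out$clipped_frac <- mean(clipped)
  out
}

#' Contrast-step stimulus
#'
#' Constant mean-level trace with a rectangular Weber-contrast step, e.g. the
#' 0.5-s, 50%-contrast light increment used to separate transient from
#' sustained responses.
#'
#' @param mean_level Mean intensity (`> 0`).
#' @param contrast Weber contrast of the step; `>= -1` (a contrast of -1
#'   steps to darkness).
#' @param step_start_s,step_dur_s Step onset time and duration in seconds.
#' @param total_dur_s Total trace duration in seconds.
#' @param dt_s Sample interval (default 1 ms).
#' @return A [stimulus_trace()].
#' @export
make_step <- function(mean_level, contrast = 0.5, step_start_s,
                      step_dur_s = 0.5, total_dur_s, dt_s = 1e-3) {
  check_scalar(mean_level, "mean_level", positive = TRUE)
  check_scalar(contrast, "contrast")
  if (contrast < -1) stop_param("contrast", "must be >= -1 (intensity >= 0)")
  check_scalar(step_start_s, "step_start_s", nonneg = TRUE)
  check_scalar(step_dur_s, "step_dur_s", positive = TRUE)
  check_scalar(total_dur_s, "total_dur_s", positive = TRUE)
  check_scalar(dt_s, "dt_s", positive = TRUE)
  n <- round(total_dur_s / dt_s)
  i0 <- round(step_start_s / dt_s) + 1L
  n_step <- round(step_dur_s / dt_s)
  if (i0 < 1L || i0 + n_step - 1L > n) {
    stop_param("step_start_s", "step interval must lie inside the trace")
  }
  values <- rep(mean_level, n)
  values[i0:(i0 + n_step - 1L)] <- max(mean_level * (1 + contrast), 0)
  stimulus_trace(values, dt_s, mean_level)
}

#' Paired-flash stimulus family
#'
#' Builds, for each inter-flash interval, a trace containing two identical
#' rectangular flashes whose onsets are separated by that interval, plus one
#' companion trace containing only the first flash. The single-flash trace
#' serves as the subtraction template when isolating the second-flash
#' response (see [paired_flash_ratio()]). Defaults follow the paired-flash
#' depression protocol: 400% contrast, 10-ms flashes at 50/100/200/400-ms
#' intervals.
#'
#' @param mean_level Mean intensity (`> 0`).
#' @param flash_contrast Weber contrast of each flash (`> 0`), default 4.
#' @param flash_dur_s Flash duration in seconds, default 0.01.
#' @param intervals_s Numeric vector of onset-to-onset intervals in seconds;
#'   each must be `>= flash_dur_s` (flashes may not overlap).
#' @param dt_s Sample interval (default 1 ms).
#' @param pre_s Baseline time before the first flash (default 0.2 s).
#' @param post_s Time after the latest possible second flash (default 1 s).
#' @return A list with elements `paired` (named list of [stimulus_trace()],
#'   one per interval, names the interval in seconds), `single` (the
#'   single-flash template trace), `first_onset_s`, `flash_dur_s` and
#'   `intervals_s`. All traces share the same length and time base.
#' @export
make_paired_flash <- function(mean_level, flash_contrast = 4,
                              flash_dur_s = 0.01,
                              intervals_s = c(0.05, 0.1, 0.2, 0.4),
                              dt_s = 1e-3, pre_s = 0.2, post_s = 1) {
  check_scalar(mean_level, "mean_level", positive = TRUE)
  check_scalar(flash_contrast, "flash_contrast", positive = TRUE)
  check_scalar(flash_dur_s, "flash_dur_s", positive = TRUE)
  check_numeric_vector(intervals_s, "intervals_s")
  check_scalar(dt_s, "dt_s", positive = TRUE)
  if (any(intervals_s < flash_dur_s)) {
    stop_param("intervals_s", "flashes overlap: every interval must be >= flash_dur_s")
  }
  total_dur_s <- pre_s + max(intervals_s) + flash_dur_s + post_s
  n <- round(total_dur_s / dt_s)
  n_flash <- round(flash_dur_s / dt_s)
  i_first <- round(pre_s / dt_s) + 1L
  flash_level <- mean_level * (1 + flash_contrast)

  base <- rep(mean_level, n)
  single <- base
  single[i_first:(i_first + n_flash - 1L)] <- flash_level

  paired <- lapply(intervals_s, function(iv) {
    v <- single
    i2 <- i_first + round(iv / dt_s)
    v[i2:(i2 + n_flash - 1L)] <- flash_level
    stimulus_trace(v, dt_s, mean_level)
  })
  names(paired) <- as.character(intervals_s)

  list(paired = paired,
       single = stimulus_trace(single, dt_s, mean_level),
       first_onset_s = (i_first - 1L) * dt_s,
       flash_dur_s = n_flash * dt_s,
       intervals_s = intervals_s)
}
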