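# Depressing ribbon-synapse model: a single readily releasable vesicle pool
# with use-dependent depletion and first-order replenishment.
#
#   dp/dt = (P0 - p) / tau_r  -  k * max(drive - theta, 0) * p
#   R(t)  =       k * max(drive - theta, 0) * p(t)
#
# Sustained suprathreshold drive d gives the closed-form steady state
#   R_ss = k * d' * P0 / (1 + k * d' * tau_r),  d' = d - theta,
# and two brief pulses separated by Dt give the paired-pulse ratio
#   R2 / R1 ~= 1 - f * exp(-Dt / tau_r)
# where f is the per-pulse depletion fraction. Pool size plays the role of
# the ribbon-tethered vesicle complement: small pools with slow replenishment
# deplete quickly and transmit transiently; large, fast-replenishing pools
# sustain release.

#' Depressing ribbon-synapse parameters
#'
#' @param pool_size_P0 Readily releasable pool size (vesicles, `> 0`).
#' @param release_rate_k Release rate constant (1/s per unit of
#'   suprathreshold drive, `>= 0`).
#' @param drive_threshold_theta Drive level below which no release occurs
#'   (drive units). Higher thresholds make transmission more transient by
#'   rectifying away the sustained component of the drive.
#' @param replenish_tau_s Pool replenishment time constant (s, `> 0`); with
#'   zero drive the occupancy relaxes to `pool_size_P0` exponentially with
#'   this time constant.
#' @return An object of class `depressing_synapse`.
#' @seealso [simulate_depressing_release()]
#' @export
depressing_synapse <- function(pool_size_P0, release_rate_k,
                               drive_threshold_theta = 0,
                               replenish_tau_s) {
  check_scalar(pool_size_P0, "pool_size_P0", positive = TRUE)
  check_scalar(release_rate_k, "release_rate_k", nonneg = TRUE)
  check_scalar(drive_threshold_theta, "drive_threshold_theta")
  check_scalar(replenish_tau_s, "replenish_tau_s", positive = TRUE)
  structure(list(pool_size_P0 = pool_size_P0,
                 release_rate_k = release_rate_k,
                 drive_threshold_theta = drive_threshold_theta,
                 replenish_tau_s = replenish_tau_s),
            class = "depressing_synapse")
}

#' @export
print.depressing_synapse <- function(x, ...) {
  cat(sprintf(
    "<depressing_synapse> P0 = %g vesicles, k = %g /s/drive, theta = %g, tau_r = %g s\n",
    x$pool_size_P0, x$release_rate_k, x$drive_threshold_theta,
    x$replenish_tau_s))
  invisible(x)
}

#' Simulate vesicle release from a depressing synapse
#'
#' Forward-Euler integration of the single-pool depletion model. The
#' occupancy is guaranteed to stay within `[0, P0]` whenever the stability
#' guard holds; if the per-step decrement `(1/tau_r + k * drive') * dt`
#' reaches 1 the integration aborts with a suggestion to reduce `dt_s`.
#'
#' @param drive Numeric vector of presynaptic drive sampled at `dt_s`.
#' @param dt_s Integration step (s); default `1e-4` resolves the fastest
#'   release transients used here.
#' @param syn A [depressing_synapse()].
#' @param p_init Initial pool occupancy; defaults to the full pool.
#' @return List with numeric vectors `release_rate` (vesicles/s) and
#'   `occupancy` (vesicles), plus `dt_s`.
#' @export
simulate_depressing_release <- function(drive, dt_s = 1e-4, syn,
                                        p_init = syn$pool_size_P0) {
  check_numeric_vector(drive, "drive")
  check_scalar(dt_s, "dt_s", positive = TRUE)
  stopifnot(inherits(syn, "depressing_synapse"))
  check_scalar(p_init, "p_init", nonneg = TRUE)
  if (p_init > syn$pool_size_P0) stop_param("p_init", "exceeds pool size")

  ex <- pmax(drive - syn$drive_threshold_theta, 0) * syn$release_rate_k
  decay <- (1 / syn$replenish_tau_s + ex) * dt_s
  if (any(decay >= 1)) {
    stop(sprintf(paste0(
      "integration unstable: (1/tau_r + k * drive') * dt reaches %.3g >= 1; ",
      "use dt_s <= %.3g s"), max(decay),
      0.5 * dt_s / max(decay)), call. = FALSE)
  }

  n <- length(drive)
  p <- numeric(n)
  rel <- numeric(n)
  refill <- dt_s * syn$pool_size_P0 / syn$replenish_tau_s
  pc <- p_init
  for (i in seq_len(n)) {
    p[i] <- pc
    rel[i] <- ex[i] * pc
    pc <- pc * (1 - decay[i]) + refill
  }
  list(release_rate = rel, occupancy = p, dt_s = dt_s)
}

#' Closed-form steady-state release rate
#'
#' For constant suprathreshold drive `d`, the single-pool model relaxes to
#' `R_ss = k d' P0 / (1 + k d' tau_r)` with `d' = d - theta`. Exposed so
#' simulations can be checked against the analytic value.
#'
#' @param syn A [depressing_synapse()].
#' @param drive Constant drive level.
#' @return Steady-state release rate (vesicles/s).
#' @export
steady_state_release <- function(syn, drive) {
  stopifnot(inherits(syn, "depressing_synapse"))
  check_scalar(drive, "drive")
  d <- max(drive - syn$drive_threshold_theta, 0)
  syn$release_rate_k * d * syn$pool_size_P0 /
    (1 + syn$release_rate_k * d * syn$replenish_tau_s)
}

#' Simulate an excitatory postsynaptic current from a release-rate trace
#'
#' Convolves vesicle release with a unit-peak exponential quantal kernel and
#' scales by the quantal amplitude; inward current is negative, baseline 0.
#' A single released vesicle produces a peak of `-quantal_amp_pA`.
#'
#' @param release_rate Numeric vector, vesicles/s, sampled at `dt_s`.
#' @param dt_s Sample interval (s).
#' @param quantal_amp_pA Peak amplitude of the quantal event (pA, `> 0`).
#' @param quantal_kernel_tau_s Decay time constant of the quantal event (s).
#' @param noise_sd SD of additive Gaussian current noise (pA).
#' @param seed Optional seed for the noise.
#' @return Numeric current vector in pA (inward negative).
#' @export
simulate_epsc <- function(release_rate, dt_s = 1e-4, quantal_amp_pA = 5,
                          quantal_kernel_tau_s = 2e-3, noise_sd = 0,
                          seed = NULL) {
  check_numeric_vector(release_rate, "release_rate")
  check_scalar(dt_s, "dt_s", positive = TRUE)
  check_scalar(quantal_amp_pA, "quantal_amp_pA", positive = TRUE)
  check_scalar(quantal_kernel_tau_s, "quantal_kernel_tau_s", positive = TRUE)
  check_scalar(noise_sd, "noise_sd", nonneg = TRUE)
  t_k <- seq(0, 8 * quantal_kernel_tau_s, by = dt_s)
  kern <- exp(-t_k / quantal_kernel_tau_s)     # unit peak
  i_t <- -quantal_amp_pA * fft_causal_conv(release_rate * dt_s, kern)
  if (noise_sd > 0) {
    i_t <- i_t + with_local_seed(seed, stats::rnorm(length(i_t), sd = noise_sd))
  }
  i_t
}

#' Simulate a glutamate-sensor fluorescence trace
#'
#' Convolves release with a unit-area exponential sensor kernel (so steady
#' release `R` gives a steady fluorescence of `R * sensor gain`), averages
#' the continuous signal within each imaging frame and adds per-frame
#' Gaussian noise. The default frame rate matches the two-photon glutamate
#' imaging protocol (58.25 Hz).
#'
#' @param release_rate Numeric vector, vesicles/s at `dt_s`.
#' @param dt_s Sample interval of `release_rate` (s).
#' @param sensor_tau_s Sensor decay time constant (s).
#' @param frame_rate_hz Imaging frame rate (Hz), default 58.25.
#' @param noise_sd Per-frame Gaussian noise SD (a.u.).
#' @param seed Optional seed.
#' @return List with `values` (one sample per frame, a.u.), `frame_times`
#'   (frame start times, s) and `frame_rate_hz`.
#' @export
simulate_fluorescence <- function(release_rate, dt_s = 1e-4,
                                  sensor_tau_s = 0.06,
                                  frame_rate_hz = 58.25, noise_sd = 0,
                                  seed = NULL) {
  check_numeric_vector(release_rate, "release_rate")
  check_scalar(dt_s, "dt_s", positive = TRUE)
  check_scalar(sensor_tau_s, "sensor_tau_s", positive = TRUE)
  check_scalar(frame_rate_hz, "frame_rate_hz", positive = TRUE)
  check_scalar(noise_sd, "noise_sd", nonneg = TRUE)
  # exponential kernel with continuous-time area sensor_tau_s: steady
  # release R plateaus at R * sensor_tau_s
  t_k <- seq(0, 8 * sensor_tau_s, by = dt_s)
  f_cont <- fft_causal_conv(release_rate, exp(-t_k / sensor_tau_s)) * dt_s
  frame_dt <- 1 / frame_rate_hz
  duration <- length(release_rate) * dt_s
  n_frames <- floor(duration / frame_dt)
  frame_idx <- findInterval(seq_along(release_rate) * dt_s - dt_s / 2,
                            seq_len(n_frames) * frame_dt) + 1L
  keep <- frame_idx <= n_frames
  values <- as.numeric(tapply(f_cont[keep], frame_idx[keep], mean))
  if (noise_sd > 0) {
    values <- values + with_local_seed(seed, stats::rnorm(n_frames, sd = noise_sd))
  }
  list(values = values,
       frame_times = (seq_len(n_frames) - 1L) * frame_dt,
       frame_rate_hz = frame_rate_hz)
}
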