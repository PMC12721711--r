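# Ground-truth LN neurons and spiking: the generative side of the
# reverse-correlation analysis.

#' Parametric static nonlinearities
#'
#' Constructors for the two monotone output functions used by ground-truth
#' LN neurons: a piecewise-linear rectifier with threshold and gain, and a
#' cumulative-Gaussian saturating function.
#'
#' @param threshold Rectifier threshold on the generator-signal axis.
#' @param gain Slope above threshold (response units per generator unit).
#' @param midpoint,slope,maximum Cumulative-Gaussian midpoint, slope
#'   (Gaussian SD) and asymptotic maximum.
#' @return A function of one numeric argument with class `static_nl_fun`.
#' @examples
#' f <- rectifier_nl(threshold = 0, gain = 2)
#' f(c(-1, 0, 1))  # 0 0 2
#' @export
rectifier_nl <- function(threshold = 0, gain = 1) {
  check_scalar(threshold, "threshold")
  check_scalar(gain, "gain", nonneg = TRUE)
  structure(function(x) gain * pmax(x - threshold, 0),
            class = c("static_nl_fun", "function"),
            params = list(kind = "rectifier", threshold = threshold, gain = gain))
}

#' @rdname rectifier_nl
#' @export
cgauss_nl <- function(midpoint = 0, slope = 1, maximum = 1) {
  check_scalar(midpoint, "midpoint")
  check_scalar(slope, "slope", positive = TRUE)
  check_scalar(maximum, "maximum", positive = TRUE)
  structure(function(x) maximum * stats::pnorm(x, mean = midpoint, sd = slope),
            class = c("static_nl_fun", "function"),
            params = list(kind = "cgauss", midpoint = midpoint, slope = slope,
                          maximum = maximum))
}

#' Ground-truth LN neuron
#'
#' Bundles a causal linear filter with a monotone static output function;
#' the generative model the reverse-correlation estimators assume.
#'
#' @param filter A [linear_filter()].
#' @param nonlinearity A monotone function mapping generator signal to
#'   response (e.g. [rectifier_nl()]); `identity` is allowed.
#' @param output_units Label only ("mV", "pA", "a.u.").
#' @return An object of class `ground_truth_ln`.
#' @export
ground_truth_ln <- function(filter, nonlinearity = identity,
                            output_units = "a.u.") {
  stopifnot(inherits(filter, "linear_filter"), is.function(nonlinearity))
  structure(list(filter = filter, nonlinearity = nonlinearity,
                 output_units = output_units),
            class = "ground_truth_ln")
}

#' Simulate an LN response to a stimulus
#'
#' Applies the model's filter to the stimulus contrast, passes the generator
#' signal through the static nonlinearity and adds white Gaussian noise.
#'
#' @param model A [ground_truth_ln()].
#' @param stim A [stimulus_trace()] with the same `dt_s` as the filter.
#' @param noise_sd SD of additive Gaussian noise (response units).
#' @param seed Optional seed for the noise.
#' @return Numeric response vector with attribute `burn_in` (samples covering
#'   the first filter length, to discard before model fitting).
#' @export
simulate_ln_response <- function(model, stim, noise_sd = 0, seed = NULL) {
  stopifnot(inherits(model, "ground_truth_ln"))
  check_scalar(noise_sd, "noise_sd", nonneg = TRUE)
  g <- generator_signal(model$filter, stim)
  r <- model$nonlinearity(as.numeric(g))
  if (noise_sd > 0) {
    r <- r + with_local_seed(seed, stats::rnorm(length(r), sd = noise_sd))
  }
  attr(r, "burn_in") <- attr(g, "burn_in")
  r
}

#' Inhomogeneous Poisson spike generation with refractoriness
#'
#' Thinning algorithm: candidate events are drawn from a homogeneous Poisson
#' process at the peak rate and accepted with probability `rate(t) / max rate`;
#' accepted events closer than the absolute refractory period to the previous
#' spike are discarded.
#'
#' @param drive Numeric vector: the time-varying drive sampled at `dt_s`.
#' @param dt_s Sample interval of `drive` (s).
#' @param rate_map Monotone function mapping drive to firing rate in Hz
#'   (must return values `>= 0`), or a precomputed numeric rate vector the
#'   same length as `drive`.
#' @param refractory_s Absolute refractory period (s), `>= 0`.
#' @param seed Optional seed.
#' @return An object of class `spike_train`: list with `spike_times` (s,
#'   strictly increasing, in `[0, duration)`) and `duration` (s).
#' @export
simulate_spikes <- function(drive, dt_s, rate_map = rectifier_nl(0, 1),
                            refractory_s = 0, seed = NULL) {
  check_numeric_vector(drive, "drive")
  check_scalar(dt_s, "dt_s", positive = TRUE)
  check_scalar(refractory_s, "refractory_s", nonneg = TRUE)
  rate <- if (is.function(rate_map)) rate_map(drive) else as.numeric(rate_map)
  if (length(rate) != length(drive)) {
    stop_param("rate_map", "rate vector must match drive length")
  }
  if (any(rate < 0)) stop_param("rate_map", "rates must be >= 0")
  duration <- length(drive) * dt_s
  rmax <- max(rate)
  if (rmax == 0) {
    return(structure(list(spike_times = numeric(0), duration = duration),
                     class = "spike_train"))
  }
  spike_times <- with_local_seed(seed, {
    n_cand <- stats::rpois(1, rmax * duration)
    cand <- sort(stats::runif(n_cand, 0, duration))
    idx <- pmin(floor(cand / dt_s) + 1L, length(rate))
    keep <- stats::runif(n_cand) < rate[idx] / rmax
    cand <- cand[keep]
    if (refractory_s > 0 && length(cand) > 1) {
      out <- numeric(length(cand))
      k <- 0L
      last <- -Inf
      for (tt in cand) {
        if (tt - last >= refractory_s) {
          k <- k + 1L
          out[k] <- tt
          last <- tt
        }
      }
      cand <- out[seq_len(k)]
    }
    cand
  })
  structure(list(spike_times = spike_times, duration = duration),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %d spikes over %.3g s (mean rate %.2f Hz)\n",
              length(x$spike_times), x$duration,
              length(x$spike_times) / x$duration))
  invisible(x)
}
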