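# Reverse-correlation estimation of LN models: spike-triggered averaging,
# spectral deconvolution of continuous responses, quantile-binned static
# nonlinearities, and prediction scoring.

#' Spike-triggered average
#'
#' Averages the stimulus contrast preceding each spike:
#' `STA[k] = mean over spikes of contrast(t_spike - (k - 1) * dt)`.
#' Spikes earlier than one analysis window after stimulus onset are excluded
#' (their count is attached as attribute `n_excluded`); the mean contrast is
#' subtracted. The default implementation computes all spike-lag sums at
#' once via FFT cross-correlation of the contrast with the binned spike
#' count; `method = "direct"` averages the stimulus segments spike by spike
#' and is retained as the independent slow path (the two agree to numerical
#' round-off).
#'
#' @param stim A [stimulus_trace()].
#' @param spikes A `spike_train` (see [simulate_spikes()]) or numeric vector
#'   of spike times in seconds.
#' @param window_s Analysis window (s): the STA spans lags `0 ... window_s`.
#' @param method `"fft"` (default) or `"direct"`.
#' @return A [linear_filter()] on the causal lag axis with attributes
#'   `n_spikes` (spikes used) and `n_excluded`.
#' @export
compute_sta <- function(stim, spikes, window_s = 0.5,
                        method = c("fft", "direct")) {
  stopifnot(inherits(stim, "stimulus_trace"))
  method <- match.arg(method)
  check_scalar(window_s, "window_s", positive = TRUE)
  spike_times <- if (inherits(spikes, "spike_train")) spikes$spike_times else as.numeric(spikes)
  if (anyNA(spike_times)) stop_param("spikes", "spike times must be finite")

  dt <- stim$dt_s
  c_t <- contrast(stim)
  c_t <- c_t - mean(c_t)
  n <- length(c_t)
  K <- round(window_s / dt)
  if (K < 2) stop_param("window_s", "must span at least 2 samples")

  # sample index whose time bin contains each spike
  idx <- floor(spike_times / dt) + 1L
  usable <- idx >= K & idx <= n
  n_excluded <- sum(!usable)
  idx <- idx[usable]
  if (length(idx) == 0) {
    stop("no usable spikes: all spikes fall before one window length or after the stimulus",
         call. = FALSE)
  }

  if (method == "direct") {
    acc <- numeric(K)
    for (i in idx) acc <- acc + c_t[i - (0:(K - 1L))]
    sta <- acc / length(idx)
  } else {
    cnt <- tabulate(idx, nbins = n)
    # sum_i c[i - k] = cross-correlation of contrast with spike counts at lag k
    nfft <- stats::nextn(n + K, 2L)
    C <- stats::fft(c(c_t, numeric(nfft - n)))
    S <- stats::fft(c(cnt, numeric(nfft - n)))
    cc <- Re(stats::fft(C * Conj(S), inverse = TRUE)) / nfft
    # lag k >= 0 lives at position nfft - k (modulo), lag 0 at position 1
    sta <- cc[c(1L, nfft - seq_len(K - 1L) + 1L)] / length(idx)
  }
  out <- linear_filter(sta, dt)
  attr(out, "n_spikes") <- length(idx)
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Estimate a linear filter by spectral deconvolution
#'
#' Reverse correlation for continuous responses: the cross-spectrum of
#' stimulus contrast and response is divided by the stimulus power spectrum,
#' `F(w) = conj(S(w)) R(w) / (|S(w)|^2 + eps)`, inverse-transformed and
#' truncated to the filter length. The division is regularized by
#' `eps = reg_frac * max |S(w)|^2` and restricted to the band where the
#' stimulus has power: components above `bandwidth_hz` are zeroed before
#' inversion (the deconvolution is blind there). The response is
#' mean-subtracted, so the estimate is invariant to baseline shifts.
#'
#' @param stim A [stimulus_trace()].
#' @param response Numeric response vector, same length and `dt` as `stim`.
#' @param filter_len_s Length of the returned causal filter (s), default 0.5.
#' @param bandwidth_hz Band limit for the inversion; defaults to the
#'   stimulus' recorded bandwidth, or Nyquist if none is recorded.
#' @param reg_frac Regularization fraction of the peak stimulus power
#'   (default `1e-6`).
#' @return A [linear_filter()] of `round(filter_len_s / dt)` taps.
#' @export
estimate_linear_filter <- function(stim, response, filter_len_s = 0.5,
                                   bandwidth_hz = NULL, reg_frac = 1e-6) {
  stopifnot(inherits(stim, "stimulus_trace"))
  response <- as.numeric(response)
  check_numeric_vector(response, "response", min_len = 2L)
  check_scalar(filter_len_s, "filter_len_s", positive = TRUE)
  check_scalar(reg_frac, "reg_frac", positive = TRUE)
  dt <- stim$dt_s
  n <- length(stim$values)
  if (length(response) != n) {
    stop_param("response", "must have the same length as the stimulus")
  }
  K <- round(filter_len_s / dt)
  if (K < 2) stop_param("filter_len_s", "must span at least 2 samples")
  if (n < 10 * K) {
    stop_param("stim", "recording must be at least 10 filter lengths long")
  }
  if (is.null(bandwidth_hz)) bandwidth_hz <- stim$bandwidth_hz
  if (is.null(bandwidth_hz)) bandwidth_hz <- 1 / (2 * dt)

  c_t <- contrast(stim)
  c_t <- c_t - mean(c_t)
  r_t <- response - mean(response)

  S <- stats::fft(c_t)
  R <- stats::fft(r_t)
  P <- Mod(S)^2
  in_band_peak <- max(P)
  if (in_band_peak <= 0) {
    stop("stimulus has no power: deconvolution is ill-conditioned", call. = FALSE)
  }
  H <- Conj(S) * R / (P + reg_frac * in_band_peak)

  fs <- 1 / dt
  freq <- (seq_len(n) - 1L) / (n * dt)
  freq <- pmin(freq, fs - freq)
  out_band <- freq > bandwidth_hz
  H[out_band] <- 0 + 0i
  if (mean(P[!out_band]) <= 1e3 * .Machine$double.eps * in_band_peak) {
    stop("stimulus has (near-)zero in-band power: deconvolution is ill-conditioned",
         call. = FALSE)
  }

  taps <- Re(stats::fft(H, inverse = TRUE))[seq_len(K)] / n
  linear_filter(taps, dt)
}

#' Binned static nonlinearity
#'
#' Fits the output stage of an LN model by the point-by-point comparison of
#' the generator signal (predicted filter output) with the measured
#' response, binned along the generator axis. Bins hold (near-)equal sample
#' counts (quantile bins), which keeps each bin mean equally well estimated
#' regardless of the generator-signal density; bins that end up with fewer
#' than `min_count` samples are merged with a neighbor.
#'
#' @param generator Numeric generator-signal vector (burn-in removed).
#' @param response Numeric response vector, same length.
#' @param n_bins Number of quantile bins (default 20, `>= 2`).
#' @param min_count Minimum samples per bin (default 50).
#' @return An object of class `static_nonlinearity`: list with
#'   `bin_centers` (mean generator value per bin, strictly increasing),
#'   `bin_means` (mean response per bin) and `bin_counts`.
#' @export
fit_nonlinearity <- function(generator, response, n_bins = 20,
                             min_count = 50) {
  burn <- attr(generator, "burn_in")
  generator <- drop_burn_in(generator)
  response <- as.numeric(response)
  if (!is.null(burn) && length(response) == length(generator) + burn) {
    response <- response[-seq_len(burn)]
  }
  check_numeric_vector(generator, "generator", min_len = 4L)
  if (length(response) != length(generator)) {
    stop_param("response", "must match the generator-signal length")
  }
  check_scalar(n_bins, "n_bins")
  if (n_bins < 2) stop_param("n_bins", "must be >= 2")
  if (stats::sd(generator) == 0) {
    stop_param("generator", "all generator values identical; nonlinearity undefined")
  }
  breaks <- unique(stats::quantile(generator, probs = seq(0, 1, length.out = n_bins + 1),
                                   names = FALSE, type = 7))
  if (length(breaks) < 3) stop_param("generator", "too few distinct values to bin")
  bin <- findInterval(generator, breaks, all.inside = TRUE)

  centers <- as.numeric(tapply(generator, bin, mean))
  means <- as.numeric(tapply(response, bin, mean))
  counts <- as.integer(table(bin))

  # merge undersized bins into the nearer neighbor until all pass min_count
  while (length(counts) > 2 && any(counts < min_count)) {
    i <- which.min(counts)
    j <- if (i == 1) 2L else if (i == length(counts)) i - 1L else {
      if (counts[i - 1] <= counts[i + 1]) i - 1L else i + 1L
    }
    w <- counts[c(i, j)]
    centers[j] <- sum(centers[c(i, j)] * w) / sum(w)
    means[j] <- sum(means[c(i, j)] * w) / sum(w)
    counts[j] <- sum(w)
    centers <- centers[-i]; means <- means[-i]; counts <- counts[-i]
  }
  ord <- order(centers)
  structure(list(bin_centers = centers[ord], bin_means = means[ord],
                 bin_counts = counts[ord]),
            class = "static_nonlinearity")
}

#' @export
print.static_nonlinearity <- function(x, ...) {
  cat(sprintf("<static_nonlinearity> %d bins over generator range [%.3g, %.3g]\n",
              length(x$bin_centers), min(x$bin_centers), max(x$bin_centers)))
  invisible(x)
}

#' Fitted LN model
#'
#' Couples an estimated linear filter with a binned static nonlinearity and
#' the response baseline subtracted before fitting.
#'
#' @param filter A [linear_filter()].
#' @param nonlinearity A `static_nonlinearity` (see [fit_nonlinearity()]).
#' @param response_baseline Scalar subtracted from the response before the
#'   nonlinearity was fitted; re-added by [predict_response()].
#' @return An object of class `ln_model`.
#' @export
ln_model <- function(filter, nonlinearity, response_baseline = 0) {
  stopifnot(inherits(filter, "linear_filter"),
            inherits(nonlinearity, "static_nonlinearity"))
  check_scalar(response_baseline, "response_baseline")
  structure(list(filter = filter, nonlinearity = nonlinearity,
                 response_baseline = response_baseline),
            class = "ln_model")
}

#' Fit an LN model from a stimulus-response pair
#'
#' Convenience wrapper chaining [estimate_linear_filter()],
#' [generator_signal()] and [fit_nonlinearity()]; the response mean is used
#' as the baseline.
#'
#' @inheritParams estimate_linear_filter
#' @inheritParams fit_nonlinearity
#' @return An [ln_model()].
#' @export
fit_ln_model <- function(stim, response, filter_len_s = 0.5,
                         bandwidth_hz = NULL, n_bins = 20, min_count = 50) {
  filt <- estimate_linear_filter(stim, response, filter_len_s, bandwidth_hz)
  g <- generator_signal(filt, stim)
  burn <- attr(g, "burn_in")
  baseline <- mean(response)
  nl <- fit_nonlinearity(drop_burn_in(g),
                         as.numeric(response)[-seq_len(burn)] - baseline,
                         n_bins = n_bins, min_count = min_count)
  ln_model(filt, nl, baseline)
}

#' Predict the response of a fitted LN model
#'
#' Applies the binned nonlinearity to the generator signal, interpolating
#' linearly between bin centers and extrapolating as a constant beyond the
#' end bins, then re-adds the response baseline.
#'
#' @param model An [ln_model()].
#' @param stim A [stimulus_trace()] with matching `dt_s`.
#' @return Numeric predicted response with attribute `burn_in`.
#' @export
predict_response <- function(model, stim) {
  stopifnot(inherits(model, "ln_model"))
  g <- generator_signal(model$filter, stim)
  nl <- model$nonlinearity
  y <- stats::approx(nl$bin_centers, nl$bin_means, xout = as.numeric(g),
                     rule = 2)$y + model$response_baseline
  attr(y, "burn_in") <- attr(g, "burn_in")
  y
}

#' Score an LN prediction against a measured response
#'
#' Pearson correlation between the model prediction and the trial-averaged
#' measured response, after removing the burn-in.
#'
#' @param prediction Numeric prediction (burn-in attribute honored).
#' @param measured Numeric measured (trial-mean) response, same length.
#' @return Pearson r in `[-1, 1]`.
#' @export
model_performance <- function(prediction, measured) {
  burn <- attr(prediction, "burn_in")
  prediction <- drop_burn_in(prediction)
  measured <- as.numeric(measured)
  if (!is.null(burn) && length(measured) == length(prediction) + burn) {
    measured <- measured[-seq_len(burn)]
  }
  if (length(measured) != length(prediction)) {
    stop_param("measured", "length does not match the prediction")
  }
  pearson_r(prediction, measured)
}
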