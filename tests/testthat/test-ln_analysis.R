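make_ln_cell <- function(dt = 1e-3) {
  ground_truth_ln(make_ground_truth_filter(1, 0.6, 0.015, 0.024, dt, 0.5),
                  rectifier_nl(-2, 1))
}

test_that("FFT and spike-segment STAs agree to numerical precision", {
  stim <- make_gaussian_noise(100, 0.5, 60, duration_s = 40, seed = 1)
  cell <- make_ln_cell()
  g <- generator_signal(cell$filter, stim)
  spikes <- simulate_spikes(pmax(as.numeric(g), 0), stim$dt_s,
                            rate_map = function(x) 25 * x, seed = 2)
  expect_gt(length(spikes$spike_times), 2000)
  fft_sta <- compute_sta(stim, spikes, 0.5, method = "fft")
  dir_sta <- compute_sta(stim, spikes, 0.5, method = "direct")
  expect_lt(max(abs(fft_sta$taps - dir_sta$taps)), 1e-10)
  # and both agree with the plain helper loop
  expect_equal(dir_sta$taps,
               sta_oracle(contrast(stim), spikes$spike_times, stim$dt_s, 500),
               tolerance = 1e-10)
})

test_that("the STA recovers the generating filter shape", {
  stim <- make_gaussian_noise(100, 0.5, 60, duration_s = 120, seed = 3)
  cell <- make_ln_cell()
  g <- generator_signal(cell$filter, stim)
  spikes <- simulate_spikes(pmax(as.numeric(g), 0), stim$dt_s,
                            rate_map = function(x) 20 * x,
                            refractory_s = 0.002, seed = 4)
  expect_gt(length(spikes$spike_times), 2000)
  sta <- compute_sta(stim, spikes, 0.5)
  truth <- bandlimit(c(cell$filter$taps,
                       numeric(length(stim$values) - 500)), 1e-3, 60)[1:500]
  expect_gt(cosine_sim(sta$taps, truth), 0.95)
})

test_that("STA degenerate cases: random spikes average out, one spike is exact", {
  stim <- make_gaussian_noise(100, 0.5, 60, duration_s = 120, seed = 5)
  n_sp <- 4000
  rand_spikes <- sort(runif(n_sp, 1, 119))
  sta <- compute_sta(stim, rand_spikes, 0.25)
  expect_lt(max(abs(sta$taps)), 4 * sd(contrast(stim)) / sqrt(n_sp))

  one <- compute_sta(stim, 10.0005, 0.25)
  c_t <- contrast(stim) - mean(contrast(stim))
  i <- floor(10.0005 / 1e-3) + 1
  expect_equal(one$taps, c_t[i - (0:249)], tolerance = 1e-12)
  expect_equal(attr(one, "n_spikes"), 1L)

  expect_error(compute_sta(stim, 0.01, 0.25), "no usable spikes")
})

test_that("spectral deconvolution recovers a known filter", {
  filt <- make_ground_truth_filter(1, 0.6, 0.015, 0.024, 1e-3, 0.5)
  stim <- make_gaussian_noise(100, 0.5, 60, duration_s = 120, seed = 6)
  resp <- as.numeric(generator_signal(filt, stim))
  est <- estimate_linear_filter(stim, resp, 0.5)
  truth <- bandlimit(c(filt$taps, numeric(length(stim$values) - 500)),
                     1e-3, 60)[1:500]
  rms_rel <- sqrt(mean((est$taps - truth)^2)) / max(abs(truth))
  expect_lt(rms_rel, 0.01)

  # estimation is invariant to response baseline and stimulus mean level
  est_b <- estimate_linear_filter(stim, resp + 37, 0.5)
  expect_equal(est$taps, est_b$taps, tolerance = 1e-10)
  stim2 <- stim
  stim2$values <- stim$values * 3
  stim2$mean_level <- 300
  est_m <- estimate_linear_filter(stim2, resp, 0.5)
  expect_equal(est$taps, est_m$taps, tolerance = 1e-8)
})

test_that("deconvolution identity and null systems behave", {
  # white stimulus up to Nyquist: identity system -> unit impulse at lag 0
  stim <- make_gaussian_noise(100, 0.5, 500, duration_s = 30, dt_s = 1e-3,
                              seed = 7)
  est <- estimate_linear_filter(stim, contrast(stim), 0.5)
  expect_equal(est$taps[1], 1, tolerance = 0.02)
  expect_lt(max(abs(est$taps[-1])), 0.02)

  # response independent of the stimulus: filter stays at the noise floor,
  # estimated by re-running with a circularly shifted (shuffled) response
  noise_resp <- rnorm(length(stim$values))
  est0 <- estimate_linear_filter(stim, noise_resp, 0.5)
  shuffled <- c(noise_resp[15001:30000], noise_resp[1:15000])
  floor_norm <- sqrt(sum(estimate_linear_filter(stim, shuffled, 0.5)$taps^2))
  expect_lt(sqrt(sum(est0$taps^2)), 3 * floor_norm)
})

test_that("filter-estimation error shrinks roughly as 1/sqrt(duration)", {
  filt <- make_ground_truth_filter(1, 0.6, 0.015, 0.024, 1e-3, 0.5)
  errs <- sapply(c(30, 120, 480), function(dur) {
    stim <- make_gaussian_noise(100, 0.5, 60, duration_s = dur, seed = 8)
    resp <- simulate_ln_response(ground_truth_ln(filt, identity), stim,
                                 noise_sd = 1, seed = 9)
    est <- estimate_linear_filter(stim, as.numeric(resp), 0.5)
    truth <- bandlimit(c(filt$taps, numeric(length(stim$values) - 500)),
                       1e-3, 60)[1:500]
    sqrt(mean((est$taps - truth)^2))
  })
  expect_true(all(diff(errs) < 0))
  # quadrupling duration should roughly halve the error (allow 2x slack)
  expect_lt(errs[2] / errs[1], 0.8)
  expect_lt(errs[3] / errs[2], 0.8)
})

test_that("quantile-binned nonlinearity recovers identity and rectifier shapes", {
  set.seed(10)
  g <- rnorm(50000, sd = 2)
  nl_id <- fit_nonlinearity(g, g, n_bins = 20)
  expect_equal(nl_id$bin_means, nl_id$bin_centers, tolerance = 1e-12)
  expect_gte(length(nl_id$bin_centers), 2)
  expect_true(all(diff(nl_id$bin_centers) > 0))

  # rectifier, noise-free: per-bin deviation bounded by the within-bin
  # averaging bias computed independently from the sorted samples
  rect <- function(x) pmax(x - 0.5, 0)
  nl <- fit_nonlinearity(g, rect(g), n_bins = 20)
  qs <- quantile(g, probs = seq(0, 1, length.out = 21), names = FALSE)
  bias <- sapply(seq_len(20), function(j) {
    in_bin <- g >= qs[j] & (g <= qs[j + 1])
    abs(mean(rect(g[in_bin])) - rect(mean(g[in_bin])))
  })
  dev <- abs(nl$bin_means - rect(nl$bin_centers))
  expect_true(all(dev <= max(bias) + 1e-9))

  # with Gaussian noise the bin means stay unbiased within the CLT bound
  nl_n <- fit_nonlinearity(g, rect(g) + rnorm(length(g), sd = 0.3), n_bins = 20)
  bound <- 4 * 0.3 / sqrt(min(nl_n$bin_counts))
  expect_true(all(abs(nl_n$bin_means - nl$bin_means) <= bound))

  expect_error(fit_nonlinearity(g, g, n_bins = 1), "n_bins")
  expect_error(fit_nonlinearity(rep(1, 1000), rep(1, 1000)), "identical")
})

test_that("a fitted LN model predicts held-out responses of its generator", {
  cell <- make_ln_cell()
  stim_fit <- make_gaussian_noise(100, 0.5, 60, duration_s = 240, seed = 11)
  resp_fit <- simulate_ln_response(cell, stim_fit)
  model <- fit_ln_model(stim_fit, as.numeric(resp_fit))

  stim_test <- make_gaussian_noise(100, 0.5, 60, duration_s = 30, seed = 12)
  resp_test <- simulate_ln_response(cell, stim_test)
  pred <- predict_response(model, stim_test)
  expect_gt(model_performance(pred, as.numeric(resp_test)), 0.99)

  # monotone nonlinearity preserves generator ordering
  nl <- model$nonlinearity
  expect_true(all(diff(nl$bin_means) >= -1e-9))

  # perfect and inverted predictions
  x <- as.numeric(resp_test)
  expect_equal(model_performance(x, x), 1)
  expect_equal(model_performance(x, -x), -1)
  expect_error(model_performance(rep(1, 10), rep(2, 10)), "zero variance")
})
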