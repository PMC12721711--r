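test_that("sine-period identities: unit biphasic index, half-period zero cross", {
  dt <- 1e-3
  period <- 0.16
  f <- linear_filter(sin(2 * pi * seq(0, period - dt, by = dt) / period), dt)
  expect_equal(biphasic_index(f), 1, tolerance = 1e-6)
  expect_equal(zero_cross_time(f), period / 2, tolerance = 1e-9)
})

test_that("monophasic kernels have no zero cross and index zero", {
  mono <- make_ground_truth_filter(1, 0, 0.02, 0.03, 1e-3, 0.4)
  expect_true(is.na(zero_cross_time(mono)))
  expect_equal(biphasic_index(mono), 0)
  expect_error(zero_cross_time(linear_filter(c(0, 0, 0), 1e-3)), "degenerate")
})

test_that("filter metrics are invariant to scaling and sign flip", {
  f <- make_ground_truth_filter(1, 0.6, 0.012, 0.02, 1e-3, 0.3)
  for (scale in c(0.01, 5, -1, -20)) {
    g <- linear_filter(f$taps * scale, f$dt_s)
    expect_equal(biphasic_index(g), biphasic_index(f), tolerance = 1e-12)
    expect_equal(zero_cross_time(g), zero_cross_time(f), tolerance = 1e-12)
  }
})

test_that("zero-cross matches a 1-us root-search oracle over a parameter grid", {
  dt <- 1e-3
  grid <- expand.grid(tau_rise = c(0.008, 0.012, 0.016, 0.020, 0.024),
                      ratio = c(1.3, 1.6),
                      trough = c(0.4, 0.8))
  expect_equal(nrow(grid), 20)
  for (i in seq_len(nrow(grid))) {
    tr <- grid$tau_rise[i]
    td <- tr * grid$ratio[i]
    f <- make_ground_truth_filter(1, grid$trough[i], tr, td, dt, 0.5)
    kf <- dog_kernel_fun(1, grid$trough[i], tr, td)
    zc_oracle <- zero_cross_oracle(kf, 0.5)
    expect_lt(abs(zero_cross_time(f) - zc_oracle), dt / 2)
    expect_equal(biphasic_index(f), biphasic_oracle(kf, 0.5), tolerance = 0.02)
  }
})

test_that("step kinetics: sustained and transient limits", {
  dt <- 1e-3
  onset <- 0.3
  n <- round(1.3 / dt)
  i_on <- round(onset / dt) + 1
  i_off <- i_on + round(0.5 / dt) - 1

  square <- numeric(n)
  square[i_on:i_off] <- 2
  k <- step_kinetics(square, dt, onset, 0.5)
  expect_equal(k$steady_state_pct, 100)
  expect_equal(k$time_to_peak_s, dt)
  expect_equal(k$peak_amp, 2)

  # fully decaying transient
  trans <- numeric(n)
  idx <- i_on:i_off
  trans[idx] <- exp(-(seq_along(idx) - 1) * dt / 0.03)
  kt <- step_kinetics(trans, dt, onset, 0.5)
  expect_lt(kt$steady_state_pct, 1)
  expect_gt(kt$steady_state_pct, -1)

  # invariance to baseline offset and gain; sign convention for inward currents
  k2 <- step_kinetics(-40 * trans + 7, dt, onset, 0.5)
  expect_equal(k2$steady_state_pct, kt$steady_state_pct, tolerance = 1e-9)
  expect_equal(k2$time_to_peak_s, kt$time_to_peak_s)
  expect_equal(k2$peak_amp, 40 * kt$peak_amp, tolerance = 1e-9)

  expect_error(step_kinetics(square, dt, 1.2, 0.5), "inside the trace")
})

test_that("paired-flash ratio is exact under linear superposition", {
  dt <- 1e-3
  n <- round(1.6 / dt)
  onset <- 0.2
  i1 <- round(onset / dt) + 1
  tmpl <- numeric(n)
  resp_shape <- dgamma(seq(0, 0.25, by = dt), shape = 3, scale = 0.02)
  tmpl[i1 + seq_along(resp_shape) - 1] <- resp_shape

  shift_by <- function(x, k) c(numeric(k), x[1:(length(x) - k)])
  intervals <- c(0.05, 0.1, 0.2, 0.4)
  paired <- lapply(intervals, function(iv) tmpl + shift_by(tmpl, round(iv / dt)))
  names(paired) <- intervals
  res <- paired_flash_ratio(paired, tmpl, dt, onset)
  expect_equal(res$ratios, rep(1, 4), tolerance = 1e-9)

  # constructed scaling of the second response is recovered exactly
  paired03 <- lapply(intervals, function(iv) tmpl + 0.3 * shift_by(tmpl, round(iv / dt)))
  names(paired03) <- intervals
  res03 <- paired_flash_ratio(paired03, tmpl, dt, onset)
  expect_equal(res03$ratios, rep(0.3, 4), tolerance = 1e-9)

  # works identically for negative-going (inward-current) responses
  resn <- paired_flash_ratio(lapply(paired03, function(x) -50 * x), -50 * tmpl,
                             dt, onset, intervals_s = intervals)
  expect_equal(resn$ratios, rep(0.3, 4), tolerance = 1e-9)
})

test_that("depressing synapse paired-flash ratios recover and order by interval", {
  pr <- cell_preset("ont")
  res <- preset_paired_flash(pr, intervals_s = c(0.05, 0.2, 0.8, 12))
  expect_true(all(diff(res$ratios) > 0))
  # full recovery at an interval of 20 replenishment time constants
  expect_equal(res$ratios[4], 1, tolerance = 0.01)
  expect_lt(res$ratios[1], 0.1)
})
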