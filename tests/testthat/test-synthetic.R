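test_that("ground-truth kernels have controllable lobes", {
  mono <- make_ground_truth_filter(1, 0, 0.02, 0.03, 1e-3, 0.5)
  expect_equal(biphasic_index(mono), 0)
  expect_true(is.na(zero_cross_time(mono)))

  bi <- make_ground_truth_filter(1, 0.6, 0.015, 0.025, 1e-3, 0.5)
  expect_gt(biphasic_index(bi), 0)
  expect_false(is.na(zero_cross_time(bi)))
  # first lobe is positive (ON convention)
  expect_gt(bi$taps[which.max(abs(bi$taps))], 0)

  expect_error(make_ground_truth_filter(1, 0.5, 0.02, 0.03, 1e-3, 0.05),
               "too short")
})

test_that("LN simulation reduces to the contrast trace for an impulse-identity model", {
  stim <- make_gaussian_noise(100, 0.5, 60, duration_s = 5, seed = 3)
  imp <- linear_filter(c(1, 0), stim$dt_s)
  r <- simulate_ln_response(ground_truth_ln(imp, identity), stim)
  expect_equal(as.numeric(r), contrast(stim), tolerance = 1e-12)

  # fixed seed reproducibility with noise
  model <- ground_truth_ln(make_ground_truth_filter(dt_s = stim$dt_s),
                           rectifier_nl(0, 2))
  r1 <- simulate_ln_response(model, stim, noise_sd = 0.5, seed = 11)
  r2 <- simulate_ln_response(model, stim, noise_sd = 0.5, seed = 11)
  expect_identical(as.numeric(r1), as.numeric(r2))
})

test_that("generator signal matches the time-domain convolution oracle", {
  stim <- make_gaussian_noise(100, 0.5, 60, duration_s = 2, seed = 5)
  filt <- make_ground_truth_filter(1, 0.5, 0.01, 0.02, 1e-3, 0.15)
  g <- generator_signal(filt, stim)
  expect_equal(as.numeric(g), conv_oracle(contrast(stim), filt$taps),
               tolerance = 1e-10)

  # superposition: generator signals add when filters add
  f2 <- make_ground_truth_filter(0.5, 0.2, 0.012, 0.022, 1e-3, 0.15)
  fsum <- linear_filter(filt$taps + f2$taps, 1e-3)
  expect_equal(as.numeric(generator_signal(fsum, stim)),
               as.numeric(generator_signal(filt, stim)) +
                 as.numeric(generator_signal(f2, stim)),
               tolerance = 1e-10)
})

test_that("Poisson spiking has the right mean count, refractoriness and null case", {
  dt <- 1e-3
  drive <- rep(1, 20000)  # 20 s
  st <- simulate_spikes(drive, dt, rate_map = function(x) 30 * x,
                        refractory_s = 0, seed = 21)
  expect_lt(abs(length(st$spike_times) - 600), 4 * sqrt(600))
  expect_true(all(diff(st$spike_times) > 0))

  st0 <- simulate_spikes(rep(0, 1000), dt, rate_map = function(x) x)
  expect_length(st0$spike_times, 0)

  ref <- simulate_spikes(drive, dt, rate_map = function(x) 200 * x,
                         refractory_s = 0.005, seed = 22)
  expect_gte(min(diff(ref$spike_times)), 0.005)

  expect_error(simulate_spikes(drive, dt, rate_map = function(x) -x), ">= 0")
})

test_that("pool depletion matches its closed-form steady state", {
  syn <- depressing_synapse(100, 20, 0.1, 0.3)
  dt <- 1e-4
  drive <- rep(1.1, round(8 * 0.3 / dt))     # > 5 tau_r of constant drive
  sim <- simulate_depressing_release(drive, dt, syn)
  r_ss <- steady_state_release(syn, 1.1)
  expect_equal(tail(sim$release_rate, 1), r_ss, tolerance = 0.01)
  # matches a 10x finer integration at the end point
  fine <- simulate_depressing_release(rep(1.1, round(8 * 0.3 / 1e-5)), 1e-5, syn)
  expect_equal(tail(sim$release_rate, 1), tail(fine$release_rate, 1),
               tolerance = 0.01)
})

test_that("subthreshold drive releases nothing and the pool stays full", {
  syn <- depressing_synapse(50, 30, drive_threshold_theta = 2,
                            replenish_tau_s = 0.2)
  sim <- simulate_depressing_release(runif(5000), 1e-4, syn)
  expect_true(all(sim$release_rate == 0))
  expect_true(all(sim$occupancy == 50))
})

test_that("pool occupancy stays within [0, P0] for arbitrary drives", {
  set.seed(33)
  for (rep_i in 1:5) {
    syn <- depressing_synapse(runif(1, 10, 200), runif(1, 5, 80),
                              runif(1, 0, 0.5), runif(1, 0.05, 1))
    drive <- abs(rnorm(4000, sd = 2))
    sim <- simulate_depressing_release(drive, 1e-4, syn)
    expect_true(all(sim$occupancy >= 0))
    expect_true(all(sim$occupancy <= syn$pool_size_P0 + 1e-12))
  }
})

test_that("paired pulses follow the impulse-approximation recovery curve", {
  # brief 1-ms pulses; per-pulse depletion fraction f = 1 - exp(-k * d * w)
  syn <- depressing_synapse(100, 400, 0, 0.15)
  dt <- 1e-5
  d_amp <- 1.5
  w <- 1e-3
  f <- 1 - exp(-syn$release_rate_k * d_amp * w)
  released <- function(sim, i0, i1) sum(sim$release_rate[i0:i1]) * dt
  ratios <- sapply(c(0.05, 0.1, 0.2, 0.4), function(gap) {
    n <- round((0.3 + gap + 0.05) / dt)
    drive <- numeric(n)
    i1 <- round(0.1 / dt)
    i2 <- i1 + round(gap / dt)
    np <- round(w / dt)
    drive[i1:(i1 + np - 1)] <- d_amp
    drive[i2:(i2 + np - 1)] <- d_amp
    sim <- simulate_depressing_release(drive, dt, syn)
    released(sim, i2, i2 + np - 1) / released(sim, i1, i1 + np - 1)
  })
  expected <- 1 - f * exp(-c(0.05, 0.1, 0.2, 0.4) / syn$replenish_tau_s)
  expect_equal(ratios, expected, tolerance = 0.02)
  expect_true(all(diff(ratios) > 0))
})

test_that("integration converges: halving dt changes release by < 1% RMS", {
  syn <- depressing_synapse(80, 40, 0, 0.25)
  drive <- rep(c(0, 1.2), each = 5000)   # step at 0.5 s, dt 1e-4
  a <- simulate_depressing_release(drive, 1e-4, syn)$release_rate
  drive2 <- rep(c(0, 1.2), each = 10000)
  b <- simulate_depressing_release(drive2, 5e-5, syn)$release_rate
  b_on_a <- b[seq(1, length(b), by = 2)]
  rms_rel <- sqrt(mean((a - b_on_a)^2)) / sqrt(mean(a^2))
  expect_lt(rms_rel, 0.01)
})

test_that("EPSC scales with quantal content and matches the convolution oracle", {
  dt <- 1e-4
  rel <- numeric(2000)
  rel[100] <- 25 / dt   # delta release of 25 vesicles
  i_t <- simulate_epsc(rel, dt, quantal_amp_pA = 4, quantal_kernel_tau_s = 2e-3)
  expect_equal(min(i_t), -25 * 4, tolerance = 1e-6)
  # arbitrary release trace against the slow oracle
  rel2 <- abs(rnorm(500, sd = 100))
  kern <- exp(-seq(0, 8 * 2e-3, by = dt) / 2e-3)
  expect_equal(simulate_epsc(rel2, dt, 4, 2e-3),
               -4 * conv_oracle(rel2 * dt, kern), tolerance = 1e-8)
  # zero release, zero noise -> flat zero
  expect_true(all(simulate_epsc(numeric(100), dt) == 0))
})

test_that("fluorescence frames follow the sensor kernel and frame rate", {
  dt <- 1e-4
  fl <- simulate_fluorescence(rep(200, 30000), dt, sensor_tau_s = 0.06,
                              frame_rate_hz = 58.25)
  expect_equal(diff(fl$frame_times)[1], 1 / 58.25, tolerance = 1e-12)
  # plateau: steady release R -> R * (discrete kernel area)
  t_k <- seq(0, 8 * 0.06, by = dt)
  area <- sum(exp(-t_k / 0.06)) * dt
  expect_equal(tail(fl$values, 1), 200 * area, tolerance = 0.01)
  # zero release -> pure noise with the requested SD
  fl0 <- simulate_fluorescence(numeric(30000), dt, noise_sd = 1, seed = 4)
  expect_equal(mean(fl0$values), 0, tolerance = 0.2)
})

test_that("ribbon generator reproduces the type-size ratio and target r-squared", {
  big <- make_ribbon_dataset(n_per_type = 300, seed = 10)
  med <- tapply(big$volume_um3, big$bipolar_type, median)
  ratio <- med[["6"]] / med[["5i"]]
  expect_gt(ratio, 2)
  expect_lt(ratio, 3)
  expect_setequal(unique(big$target[big$bipolar_type == "5i"]), "ON-T")
  expect_setequal(unique(big$target[big$bipolar_type == "6"]), "ON-S")

  # noise-free counts: regression explains everything (up to integer rounding)
  clean <- make_ribbon_dataset(n_per_type = 100, count_noise_sd = 0, seed = 2)
  fit <- fit_ribbon_regression(clean, predictor = "volume_um3",
                               response = "vesicle_count")
  expect_gt(fit$r_squared, 0.999)

  # calibrated noise: mean r-squared across seeds near the 0.66 target
  r2 <- sapply(1:8, function(s) {
    d <- make_ribbon_dataset(n_per_type = 75, seed = 100 + s)
    fit_ribbon_regression(d)$r_squared
  })
  expect_equal(mean(r2), 0.66, tolerance = 0.05)
})
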