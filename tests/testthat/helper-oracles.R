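# Independent slow-path oracles used across the suite. These deliberately
# avoid the package's FFT/vectorized implementations: plain loops and
# closed forms only.

# O(N * K) time-domain causal convolution
conv_oracle <- function(x, kern) {
  n <- length(x)
  K <- length(kern)
  y <- numeric(n)
  for (t in seq_len(n)) {
    kk <- seq_len(min(K, t))
    y[t] <- sum(kern[kk] * x[t - kk + 1])
  }
  y
}

# spike-segment averaging STA, one spike at a time
sta_oracle <- function(contrast_t, spike_times, dt, K) {
  c_t <- contrast_t - mean(contrast_t)
  idx <- floor(spike_times / dt) + 1L
  idx <- idx[idx >= K & idx <= length(c_t)]
  acc <- numeric(K)
  for (i in idx) acc <- acc + c_t[i - (0:(K - 1L))]
  acc / length(idx)
}

# continuous-time difference-of-gammas kernel (order 5), evaluated exactly
dog_kernel_fun <- function(peak_amp, trough_amp, tau_rise, tau_damp) {
  g <- function(t, tau) ifelse(t <= 0, 0, (t / (5 * tau))^5 * exp(5 - t / tau))
  function(t) peak_amp * g(t, tau_rise) - trough_amp * g(t, tau_damp)
}

# brute-force root search on a 1-us grid: first sign change after the first
# suprathreshold extremum of the continuous kernel
zero_cross_oracle <- function(kern_fun, t_max, grid_dt = 1e-6) {
  t <- seq(grid_dt, t_max, by = grid_dt)
  v <- kern_fun(t)
  ipk <- which(abs(v) >= 0.1 * max(abs(v)))[1]
  # walk to the first extremum: first index after ipk where |v| stops growing
  s <- sign(v[ipk])
  iext <- ipk
  while (iext < length(v) && abs(v[iext + 1]) >= abs(v[iext]) &&
         sign(v[iext + 1]) == s) iext <- iext + 1
  j <- iext
  while (j < length(v) && sign(v[j]) == s) j <- j + 1
  if (sign(v[j]) == s) return(NA_real_)
  t[j - 1] + grid_dt * v[j - 1] / (v[j - 1] - v[j])
}

# fine-grid extrema of the continuous kernel -> lobe amplitude ratio |A|/|B|
biphasic_oracle <- function(kern_fun, t_max, grid_dt = 1e-6) {
  t <- seq(grid_dt, t_max, by = grid_dt)
  v <- kern_fun(t)
  B <- max(abs(v[v * sign(v[which.max(abs(v))[1]]) > 0]))
  zc <- zero_cross_oracle(kern_fun, t_max, grid_dt)
  if (is.na(zc)) return(0)
  after <- v[t > zc]
  s0 <- sign(v[which.max(abs(v))[1]])
  max(c(0, after * (-s0))) / max(abs(v))
}

cosine_sim <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))

# seed-local Gaussian draws that leave the suite's RNG stream alone
with_seed_rnorm <- function(seed, n, sd = 1) {
  withr::with_seed(seed, rnorm(n, sd = sd))
}
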