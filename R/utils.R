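#' @keywords internal
"_PACKAGE"

# Parameter checks shared across modules. All user-facing errors go through
# stop_param() so messages carry the offending argument name.

stop_param <- function(arg, msg) {
  stop(sprintf("invalid `%s`: %s", arg, msg), call. = FALSE)
}

check_scalar <- function(x, arg, positive = FALSE, nonneg = FALSE,
                         finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop_param(arg, "must be a single non-missing number")
  }
  if (finite && !is.finite(x)) stop_param(arg, "must be finite")
  if (positive && x <= 0) stop_param(arg, "must be > 0")
  if (nonneg && x < 0) stop_param(arg, "must be >= 0")
  invisible(x)
}

check_numeric_vector <- function(x, arg, min_len = 1L) {
  if (!is.numeric(x) || length(x) < min_len) {
    stop_param(arg, sprintf("must be a numeric vector of length >= %d", min_len))
  }
  if (anyNA(x) || any(!is.finite(x))) stop_param(arg, "must be finite")
  invisible(x)
}

# Run an expression with a locally seeded RNG, leaving the caller's RNG
# stream untouched. seed = NULL means "use the current stream".
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  check_scalar(seed, "seed")
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Brick-wall low-pass filter a sampled signal
#'
#' Zeroes all discrete-Fourier components at frequencies strictly above
#' `bandwidth_hz` and returns the inverse transform. Used both to synthesize
#' band-limited noise and to band-limit ground-truth kernels before in-band
#' comparisons with estimated filters.
#'
#' @param x Numeric vector, regularly sampled.
#' @param dt_s Sample interval in seconds.
#' @param bandwidth_hz Cut-off frequency in Hz; components above it are set
#'   to exactly zero (the DC component is kept).
#' @return Numeric vector of the same length as `x`.
#' @export
bandlimit <- function(x, dt_s, bandwidth_hz) {
  check_numeric_vector(x, "x", min_len = 2L)
  check_scalar(dt_s, "dt_s", positive = TRUE)
  check_scalar(bandwidth_hz, "bandwidth_hz", positive = TRUE)
  n <- length(x)
  fs <- 1 / dt_s
  freq <- (seq_len(n) - 1L) / (n * dt_s)
  freq <- pmin(freq, fs - freq)   # fold aliases onto [0, fs/2]
  X <- stats::fft(x)
  X[freq > bandwidth_hz] <- 0 + 0i
  Re(stats::fft(X, inverse = TRUE)) / n
}

# FFT linear (non-circular) convolution of a signal with a causal kernel,
# truncated to the signal length. Equivalent to
#   y[t] = sum_k kern[k + 1] * x[t - k]
# with x treated as zero before its first sample.
fft_causal_conv <- function(x, kern) {
  n <- length(x)
  m <- length(kern)
  nfft <- stats::nextn(n + m - 1L, 2L)
  X <- stats::fft(c(x, numeric(nfft - n)))
  K <- stats::fft(c(kern, numeric(nfft - m)))
  y <- Re(stats::fft(X * K, inverse = TRUE)) / nfft
  y[seq_len(n)]
}

pearson_r <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: an input has zero variance", call. = FALSE)
  }
  stats::cor(x, y)
}
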