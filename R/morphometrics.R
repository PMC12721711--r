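# Ribbon morphometry: per-type/per-target distribution summaries and the
# ribbon-volume vs vesicle-count regression.

#' Synthetic ribbon-morphometry dataset
#'
#' Generates one record per reconstructed synaptic ribbon: volumes are drawn
#' lognormally around a per-type mean (serial-EM ribbon volumes are
#' right-skewed and strictly positive) and tethered-vesicle counts scale
#' linearly with volume plus Gaussian noise, rounded and floored at zero.
#' The defaults emulate the reported morphology: type 6 ribbons ~2.5-fold
#' larger than type 5i, counts proportional to volume with the count noise
#' calibrated (via [calibrate_count_noise()]) so the volume-count regression
#' explains about two thirds of the variance.
#'
#' @param n_per_type Ribbons per bipolar type.
#' @param type_volume_means Named numeric vector of mean ribbon volumes
#'   (um^3) per bipolar type; names become the `bipolar_type` labels.
#' @param volume_cv Coefficient of variation of volumes within a type.
#' @param slope_vesicles_per_volume Ground-truth vesicles per um^3 (`> 0`).
#' @param count_noise_sd SD of the additive Gaussian count noise; `NULL`
#'   (default) calibrates it with [calibrate_count_noise()] to
#'   `target_r2`.
#' @param target_r2 Regression r-squared targeted when auto-calibrating the
#'   count noise (default 0.66).
#' @param seed Optional seed.
#' @return A data frame with columns `volume_um3`, `vesicle_count`,
#'   `bipolar_type`, `target` (type 5i ribbons are presynaptic to transient
#'   ON-T dendrites, type 6 to sustained ON-S; other types `"unassigned"`),
#'   plus attributes `slope_truth` and `count_noise_sd`.
#' @export
make_ribbon_dataset <- function(n_per_type = 75,
                                type_volume_means = c("5i" = 0.0015,
                                                      "6" = 0.00375),
                                volume_cv = 0.45,
                                slope_vesicles_per_volume = 143000,
                                count_noise_sd = NULL,
                                target_r2 = 0.66,
                                seed = NULL) {
  check_scalar(n_per_type, "n_per_type", positive = TRUE)
  check_numeric_vector(type_volume_means, "type_volume_means")
  if (is.null(names(type_volume_means)) || any(names(type_volume_means) == "")) {
    stop_param("type_volume_means", "must be a named vector of per-type means")
  }
  if (any(type_volume_means <= 0)) stop_param("type_volume_means", "means must be > 0")
  check_scalar(volume_cv, "volume_cv", positive = TRUE)
  check_scalar(slope_vesicles_per_volume, "slope_vesicles_per_volume",
               positive = TRUE)
  if (is.null(count_noise_sd)) {
    count_noise_sd <- calibrate_count_noise(type_volume_means, volume_cv,
                                            slope_vesicles_per_volume,
                                            target_r2)
  }
  check_scalar(count_noise_sd, "count_noise_sd", nonneg = TRUE)

  target_of <- function(type) {
    switch(type, "5i" = "ON-T", "6" = "ON-S", "unassigned")
  }
  sdlog <- sqrt(log(1 + volume_cv^2))
  df <- with_local_seed(seed, {
    rows <- lapply(names(type_volume_means), function(type) {
      m <- type_volume_means[[type]]
      vol <- stats::rlnorm(n_per_type, meanlog = log(m) - sdlog^2 / 2,
                           sdlog = sdlog)
      cnt <- round(slope_vesicles_per_volume * vol +
                     stats::rnorm(n_per_type, sd = count_noise_sd))
      data.frame(volume_um3 = vol,
                 vesicle_count = pmax(cnt, 0),
                 bipolar_type = type,
                 target = target_of(type),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  rownames(df) <- NULL
  attr(df, "slope_truth") <- slope_vesicles_per_volume
  attr(df, "count_noise_sd") <- count_noise_sd
  df
}

#' Variance-matching count-noise calibration
#'
#' For counts generated as `slope * volume + noise`, the population
#' r-squared of the volume-count regression is
#' `Var(slope * V) / (Var(slope * V) + sigma^2)`. This solves for the noise
#' SD that yields a requested r-squared, using the analytic variance of the
#' equal-weight lognormal mixture over types.
#'
#' @inheritParams make_ribbon_dataset
#' @return Count-noise SD (vesicles).
#' @export
calibrate_count_noise <- function(type_volume_means, volume_cv,
                                  slope_vesicles_per_volume,
                                  target_r2 = 0.66) {
  check_scalar(target_r2, "target_r2", positive = TRUE)
  if (target_r2 >= 1) stop_param("target_r2", "must be < 1")
  m <- as.numeric(type_volume_means)
  within_var <- mean((m * volume_cv)^2)        # per-type lognormal variance
  between_var <- mean(m^2) - mean(m)^2
  var_v <- within_var + between_var
  var_signal <- slope_vesicles_per_volume^2 * var_v
  sqrt(var_signal * (1 - target_r2) / target_r2)
}

#' Ribbon volume-count linear regression
#'
#' Ordinary least squares between ribbon volume and tethered-vesicle count.
#' The default direction regresses volume (um^3) on vesicle count, which
#' makes the slope the added ribbon volume per tethered vesicle (order
#' 1e-6 um^3); the direction is explicit because a slope is only
#' interpretable with its regressor stated.
#'
#' @param records Data frame with columns `volume_um3` and `vesicle_count`
#'   (e.g. from [make_ribbon_dataset()] or [read_ribbon_table()]).
#' @param predictor,response Column names; default `vesicle_count` ->
#'   `volume_um3`.
#' @return A list of class `regression_fit`: `slope`, `intercept`,
#'   `r_squared`, `p_value_slope`, `n`, `predictor`, `response`.
#' @export
fit_ribbon_regression <- function(records, predictor = "vesicle_count",
                                  response = "volume_um3") {
  if (!is.data.frame(records)) stop_param("records", "must be a data frame")
  for (col in c(predictor, response)) {
    if (!col %in% names(records)) {
      stop_param("records", sprintf("missing column `%s`", col))
    }
  }
  x <- as.numeric(records[[predictor]])
  y <- as.numeric(records[[response]])
  n <- length(x)
  if (n < 3) stop_param("records", "need at least 3 records")
  if (stats::sd(x) == 0) stop_param("predictor", "constant predictor; regression degenerate")

  fit <- stats::lm(y ~ x)
  # exact-line input makes summary.lm warn about a perfect fit; that case is
  # legitimate here (r^2 = 1), so silence only that message
  sm <- withCallingHandlers(summary(fit), warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w))) {
      invokeRestart("muffleWarning")
    }
  })
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = sm$r.squared,
                 p_value_slope = unname(sm$coefficients[2, 4]),
                 n = n, predictor = predictor, response = response),
            class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf(
    "<regression_fit> %s ~ %s: slope = %.4g, r^2 = %.3f, p = %.3g (n = %d)\n",
    x$response, x$predictor, x$slope, x$r_squared, x$p_value_slope, x$n))
  invisible(x)
}

#' Per-group distribution summaries
#'
#' Median, quartiles (linear-interpolation convention, `quantile` type 7)
#' and 1.5-IQR whiskers (clipped to the data range) of a morphometric value
#' per group -- the numbers a violin/box summary displays.
#'
#' @param records Data frame of ribbon records.
#' @param group_by Grouping column, `"bipolar_type"` (default) or
#'   `"target"`.
#' @param value Value column, `"volume_um3"` (default) or `"vesicle_count"`.
#' @return Data frame with one row per group: `group`, `n`, `median`, `q25`,
#'   `q75`, `whisker_lo`, `whisker_hi`.
#' @export
summarize_groups <- function(records, group_by = "bipolar_type",
                             value = "volume_um3") {
  if (!is.data.frame(records) || nrow(records) == 0) {
    stop_param("records", "must be a non-empty data frame")
  }
  for (col in c(group_by, value)) {
    if (!col %in% names(records)) {
      stop_param("records", sprintf("missing column `%s`", col))
    }
  }
  groups <- split(as.numeric(records[[value]]), records[[group_by]])
  out <- lapply(names(groups), function(gname) {
    v <- groups[[gname]]
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    iqr <- q[3] - q[1]
    data.frame(group = gname, n = length(v),
               median = q[2], q25 = q[1], q75 = q[3],
               whisker_lo = max(min(v), q[1] - 1.5 * iqr),
               whisker_hi = min(max(v), q[3] + 1.5 * iqr),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
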