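# End-to-end reproducible runs: simulate the preset cells, fit LN models,
# quantify kinetics and depression, and emit a tidy metrics table plus
# provenance. Trace and table files are plain CSV; metadata rides in
# '#'-prefixed header comments so files round-trip losslessly.

fmt_num <- function(x) sprintf("%.17g", x)

#' Write / read a trace CSV
#'
#' Traces are stored as two-column CSV (`time_s`, `value`) preceded by a
#' single comment line `# key=value ...` carrying `dt_s` and, for stimuli,
#' `mean_level`, `bandwidth_hz` and `seed`. Values are written with 17
#' significant digits, so a write-read round trip reproduces the numbers
#' bit-exactly.
#'
#' @param x A [stimulus_trace()] or numeric vector.
#' @param path Output file path.
#' @param dt_s Sample interval; required when `x` is a bare numeric vector.
#' @return `write_trace` returns `path` invisibly. `read_trace` returns a
#'   [stimulus_trace()] when the header carries a mean level, otherwise a
#'   list with `values` and `dt_s`.
#' @export
write_trace <- function(x, path, dt_s = NULL) {
  if (inherits(x, "stimulus_trace")) {
    meta <- c(type = "stimulus_trace", dt_s = fmt_num(x$dt_s),
              mean_level = fmt_num(x$mean_level))
    if (!is.null(x$bandwidth_hz)) meta["bandwidth_hz"] <- fmt_num(x$bandwidth_hz)
    if (!is.null(x$seed)) meta["seed"] <- fmt_num(x$seed)
    values <- x$values
    dt_s <- x$dt_s
  } else {
    if (is.null(dt_s)) stop_param("dt_s", "required for a bare numeric trace")
    check_scalar(dt_s, "dt_s", positive = TRUE)
    values <- as.numeric(x)
    meta <- c(type = "trace", dt_s = fmt_num(dt_s))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", paste(names(meta), meta, sep = "=", collapse = " ")), con)
  writeLines("time_s,value", con)
  t_s <- (seq_along(values) - 1) * dt_s
  writeLines(paste(fmt_num(t_s), fmt_num(values), sep = ","), con)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop_param("path", sprintf("no such file: %s", path))
  lines <- readLines(path)
  if (length(lines) < 3 || !startsWith(lines[1], "# ")) {
    stop(sprintf("%s: not a trace file (missing metadata header)", path),
         call. = FALSE)
  }
  kv <- strsplit(strsplit(sub("^# ", "", lines[1]), " ")[[1]], "=")
  meta <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  body <- lines[-(1:2)]
  parts <- strsplit(body, ",", fixed = TRUE)
  bad <- which(lengths(parts) != 2)
  vals <- suppressWarnings(as.numeric(vapply(parts, function(p) p[2], "")))
  bad <- sort(unique(c(bad, which(!is.finite(vals)))))
  if (length(bad) > 0) {
    stop(sprintf("%s: malformed or non-finite value at data row %s", path,
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  dt_s <- as.numeric(meta[["dt_s"]])
  if (identical(unname(meta["type"]), "stimulus_trace")) {
    out <- stimulus_trace(vals, dt_s, mean_level = as.numeric(meta[["mean_level"]]),
                          bandwidth_hz = if ("bandwidth_hz" %in% names(meta))
                            as.numeric(meta[["bandwidth_hz"]]) else NULL)
    if ("seed" %in% names(meta)) out$seed <- as.numeric(meta[["seed"]])
    out
  } else {
    list(values = vals, dt_s = dt_s)
  }
}

#' Write / read a ribbon-morphometry table
#'
#' Plain CSV with columns `volume_um3`, `vesicle_count`, `bipolar_type`,
#' `target`.
#'
#' @param records Ribbon data frame (see [make_ribbon_dataset()]).
#' @param path File path.
#' @return `write_ribbon_table` returns `path` invisibly;
#'   `read_ribbon_table` returns the data frame.
#' @export
write_ribbon_table <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ribbon_table
#' @export
read_ribbon_table <- function(path) {
  if (!file.exists(path)) stop_param("path", sprintf("no such file: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(volume_um3 = "numeric",
                                       vesicle_count = "integer",
                                       bipolar_type = "character",
                                       target = "character"))
  need <- c("volume_um3", "vesicle_count", "bipolar_type", "target")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop(sprintf("%s: missing column(s) %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  bad <- which(!is.finite(df$volume_um3) | !is.finite(df$vesicle_count))
  if (length(bad) > 0) {
    stop(sprintf("%s: non-finite value at data row %s", path,
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  df
}

#' Run configuration for a simulated experiment
#'
#' Collects every parameter of an end-to-end run; all randomness is pinned
#' by `seed` (per-cell sub-seeds are derived deterministically from it).
#' Configurations round-trip through JSON unchanged, so a saved config
#' reproduces its run byte-for-byte.
#'
#' @param presets Character vector of preset names (see [cell_preset()]).
#' @param seed Base integer seed.
#' @param n_cells_per_preset Simulated cells per preset.
#' @param noise_duration_s Noise-stimulus duration used for LN fitting (s).
#' @param contrast_sd,bandwidth_hz Noise stimulus parameters.
#' @param dt_s Analysis sample interval for LN fitting (s).
#' @param filter_len_s,n_bins LN estimation parameters.
#' @param response_noise_sd Additive response noise during fitting
#'   (response units).
#' @param n_trials Repeats averaged for the model-performance correlation.
#' @param pf_intervals_s Paired-flash intervals (s).
#' @return A list of class `run_config`.
#' @export
run_config <- function(presets = c("ont", "ons"), seed = 1,
                       n_cells_per_preset = 3, noise_duration_s = 60,
                       contrast_sd = 0.5, bandwidth_hz = 60, dt_s = 1e-3,
                       filter_len_s = 0.5, n_bins = 20,
                       response_noise_sd = 0.05, n_trials = 5,
                       pf_intervals_s = c(0.05, 0.1, 0.2, 0.4)) {
  presets <- match.arg(presets, c("ont", "ons"), several.ok = TRUE)
  check_scalar(seed, "seed")
  check_scalar(n_cells_per_preset, "n_cells_per_preset", positive = TRUE)
  check_scalar(noise_duration_s, "noise_duration_s", positive = TRUE)
  structure(list(presets = presets, seed = as.integer(seed),
                 n_cells_per_preset = as.integer(n_cells_per_preset),
                 noise_duration_s = noise_duration_s,
                 contrast_sd = contrast_sd, bandwidth_hz = bandwidth_hz,
                 dt_s = dt_s, filter_len_s = filter_len_s, n_bins = n_bins,
                 response_noise_sd = response_noise_sd,
                 n_trials = as.integer(n_trials),
                 pf_intervals_s = pf_intervals_s),
            class = "run_config")
}

# deterministic sub-seed per cell and purpose; kept well below 2^31
cell_seed <- function(base, preset_idx, cell_idx, purpose) {
  (base %% 100000L) * 10000L + preset_idx * 1000L + cell_idx * 10L + purpose
}

#' Run a simulated experiment end to end
#'
#' For every preset and simulated cell: generates a noise stimulus, fits an
#' LN model to the cell's noisy response, scores the model on a held-out
#' repeated noise stimulus, quantifies filter kinetics (zero-cross time,
#' biphasic index), runs the contrast-step and paired-flash protocols
#' through the cell's synaptic cascade, and collects one row of metrics.
#' Given the same configuration the metrics table is reproduced exactly.
#'
#' @param config A [run_config()].
#' @param out_dir Optional output directory; when given, writes
#'   `metrics.csv`, one fitted-model JSON per cell, and `manifest.json`
#'   (package version, config, file hashes).
#' @return The metrics data frame (one row per cell): `cell_id`, `preset`,
#'   `seed`, `zero_cross_s`, `biphasic_index`, `time_to_peak_s`,
#'   `steady_state_pct`, `ln_r`, and one `pfr_<ms>ms` column per interval.
#' @export
run_experiment <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  models <- list()
  rows <- list()
  for (ip in seq_along(config$presets)) {
    pname <- config$presets[ip]
    ln_preset <- cell_preset(pname, dt_s = config$dt_s)
    cascade_preset <- cell_preset(pname)   # fine dt for synapse integration
    # the synaptic cascade is noise-free and identical across cells of a
    # preset; run the step and paired-flash protocols once
    step <- preset_step_response(cascade_preset)
    pfr <- preset_paired_flash(cascade_preset,
                               intervals_s = config$pf_intervals_s)
    for (ic in seq_len(config$n_cells_per_preset)) {
      stim <- make_gaussian_noise(100, config$contrast_sd, config$bandwidth_hz,
                                  config$noise_duration_s, config$dt_s,
                                  seed = cell_seed(config$seed, ip, ic, 1))
      resp <- simulate_ln_response(ln_preset$ln, stim,
                                   noise_sd = config$response_noise_sd,
                                   seed = cell_seed(config$seed, ip, ic, 2))
      model <- fit_ln_model(stim, as.numeric(resp),
                            filter_len_s = config$filter_len_s,
                            n_bins = config$n_bins)

      # held-out repeated noise: average n_trials noisy responses
      stim_test <- make_gaussian_noise(100, config$contrast_sd,
                                       config$bandwidth_hz,
                                       max(20, config$noise_duration_s / 3),
                                       config$dt_s,
                                       seed = cell_seed(config$seed, ip, ic, 3))
      trials <- vapply(seq_len(config$n_trials), function(tr) {
        as.numeric(simulate_ln_response(ln_preset$ln, stim_test,
                                        noise_sd = config$response_noise_sd,
                                        seed = cell_seed(config$seed, ip, ic,
                                                         3L + tr)))
      }, numeric(round(max(20, config$noise_duration_s / 3) / config$dt_s)))
      ln_r <- model_performance(predict_response(model, stim_test),
                                rowMeans(trials))

      cell_id <- sprintf("%s_%02d", pname, ic)
      row <- data.frame(
        cell_id = cell_id, preset = pname, seed = config$seed,
        zero_cross_s = zero_cross_time(model$filter),
        biphasic_index = biphasic_index(model$filter),
        time_to_peak_s = step$kinetics$time_to_peak_s,
        steady_state_pct = step$kinetics$steady_state_pct,
        ln_r = ln_r, stringsAsFactors = FALSE)
      for (j in seq_along(config$pf_intervals_s)) {
        row[[sprintf("pfr_%.0fms", 1000 * config$pf_intervals_s[j])]] <-
          pfr$ratios[j]
      }
      rows[[cell_id]] <- row
      models[[cell_id]] <- model
    }
  }
  metrics <- do.call(rbind, rows)
  rownames(metrics) <- NULL

  if (!is.null(out_dir)) {
    metrics_path <- file.path(out_dir, "metrics.csv")
    write_metrics_csv(metrics, metrics_path)
    model_paths <- vapply(names(models), function(id) {
      p <- file.path(out_dir, sprintf("model_%s.json", id))
      write_ln_model(models[[id]], p)
      p
    }, "")
    files <- c(metrics_path, model_paths)
    manifest <- list(
      package = "retinaln",
      version = as.character(utils::packageVersion("retinaln")),
      config = unclass(config),
      files = lapply(stats::setNames(files, basename(files)),
                     function(f) unname(tools::md5sum(f))))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  metrics
}

# fixed-format CSV so identical metrics serialize byte-identically
write_metrics_csv <- function(metrics, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(names(metrics), collapse = ","), con)
  body <- apply(metrics, 1, function(r) {
    paste(vapply(seq_along(r), function(j) {
      v <- r[[j]]
      if (is.numeric(metrics[[j]])) fmt_num(as.numeric(v)) else as.character(v)
    }, ""), collapse = ",")
  })
  writeLines(body, con)
  invisible(path)
}

#' Serialize / load a fitted LN model (JSON)
#'
#' Stores filter taps, sample interval, the nonlinearity bin table and the
#' response baseline in a single JSON container.
#'
#' @param model An [ln_model()].
#' @param path File path.
#' @return `write_ln_model` returns `path` invisibly; `read_ln_model`
#'   returns the [ln_model()].
#' @export
write_ln_model <- function(model, path) {
  stopifnot(inherits(model, "ln_model"))
  jsonlite::write_json(list(
    filter_taps = model$filter$taps, dt_s = model$filter$dt_s,
    bin_centers = model$nonlinearity$bin_centers,
    bin_means = model$nonlinearity$bin_means,
    bin_counts = model$nonlinearity$bin_counts,
    response_baseline = model$response_baseline),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ln_model
#' @export
read_ln_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  ln_model(linear_filter(x$filter_taps, x$dt_s),
           structure(list(bin_centers = x$bin_centers,
                          bin_means = x$bin_means,
                          bin_counts = as.integer(x$bin_counts)),
                     class = "static_nonlinearity"),
           x$response_baseline)
}
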