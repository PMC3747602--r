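#' Construct a uniformly sampled signal
#'
#' Basic container for a real-valued series sampled at a fixed rate: the raw
#' or band-limited PPG and any of its derivatives.
#'
#' @param samples Numeric vector of finite samples, length at least 2.
#' @param fs Sampling frequency in Hz (positive scalar).
#' @param label Free-text label carried through processing.
#' @param t0 Time of the first sample in seconds (defaults to 0); updated by
#'   operations that trim filter edges so sample times stay meaningful.
#' @return An object of class `sampled_signal`: a list with elements
#'   `samples`, `fs`, `label`, `t0`.
#' @export
sampled_signal <- function(samples, fs, label = "", t0 = 0) {
  samples <- as.numeric(samples)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("`fs` must be a positive finite scalar (Hz)")
  if (length(samples) < 2L)
    stop("`samples` must contain at least 2 values")
  if (any(!is.finite(samples)))
    stop("`samples` must be finite (no NA/NaN/Inf)")
  structure(list(samples = samples, fs = fs, label = as.character(label)[1L],
                 t0 = as.numeric(t0)[1L]),
            class = "sampled_signal")
}

#' @export
print.sampled_signal <- function(x, ...) {
  cat(sprintf("<sampled_signal> %s: %d samples @ %g Hz (%.3f s), t0 = %.3f s\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              length(x$samples), x$fs, length(x$samples) / x$fs, x$t0))
  invisible(x)
}

#' @export
length.sampled_signal <- function(x) length(x$samples)

#' Sample times of a signal
#' @param x A `sampled_signal`.
#' @return Numeric vector of times in seconds.
#' @export
signal_times <- function(x) {
  stopifnot(inherits(x, "sampled_signal"))
  x$t0 + (seq_along(x$samples) - 1) / x$fs
}

#' Analysis run configuration
#'
#' Bundles every tunable numeric parameter of the pipeline. The defaults are
#' the operating point of the method: band separation at 30 Hz / 0.5 Hz with
#' Hamming-window FIR orders 500 / 4000, a 5-point smooth noise-robust
#' differentiator, an equiripple low-pass with 6 Hz passband edge, 1 Hz
#' transition band and 0.001 ripple applied on the normalized 1 s base, 15
#' beats per recording, and an optimization grid of 4--14 Hz in 1 Hz steps.
#' All filter orders are tied to the canonical 1 kHz processing rate.
#'
#' @param lp_cutoff_hz Low-pass cutoff separating high-frequency noise (Hz).
#' @param hp_cutoff_hz High-pass cutoff separating the DC/drift band (Hz).
#' @param lp_order Low-pass FIR order (even; taps = order + 1).
#' @param hp_order High-pass FIR order (even).
#' @param snrd_length Differentiator kernel length (odd, >= 5).
#' @param pm_edge_hz Equiripple low-pass passband edge on the normalized base (Hz).
#' @param pm_transition_hz Width of the transition band (Hz).
#' @param pm_ripple Maximum allowed deviation in pass and stop bands.
#' @param n_beats Number of recurrences entering the ensemble average.
#' @param sweep_grid_hz Edge-frequency grid for the optimization sweep (Hz).
#' @param search_window_s Length of the systolic search window for wave
#'   detection, measured from the alignment reference on the 1 s base.
#' @param search_pre_s How far before the alignment reference the search
#'   window opens (the "a" wave precedes the 50% rising-front point).
#' @param fs Canonical processing rate (Hz); inputs at other rates are
#'   resampled to it on ingestion.
#' @return An object of class `run_config` (named list).
#' @export
run_config <- function(lp_cutoff_hz = 30, hp_cutoff_hz = 0.5,
                       lp_order = 500, hp_order = 4000,
                       snrd_length = 5,
                       pm_edge_hz = 6, pm_transition_hz = 1, pm_ripple = 0.001,
                       n_beats = 15, sweep_grid_hz = 4:14,
                       search_window_s = 0.7, search_pre_s = 0.2,
                       fs = 1000) {
  cfg <- list(lp_cutoff_hz = lp_cutoff_hz, hp_cutoff_hz = hp_cutoff_hz,
              lp_order = as.integer(lp_order), hp_order = as.integer(hp_order),
              snrd_length = as.integer(snrd_length),
              pm_edge_hz = pm_edge_hz, pm_transition_hz = pm_transition_hz,
              pm_ripple = pm_ripple, n_beats = as.integer(n_beats),
              sweep_grid_hz = as.numeric(sweep_grid_hz),
              search_window_s = search_window_s, search_pre_s = search_pre_s,
              fs = fs)
  freqs <- c(cfg$lp_cutoff_hz, cfg$hp_cutoff_hz, cfg$pm_edge_hz,
             cfg$pm_transition_hz, cfg$fs, cfg$sweep_grid_hz)
  if (any(!is.finite(freqs)) || any(freqs <= 0))
    stop("all frequencies in the configuration must be positive and finite")
  if (cfg$pm_edge_hz + cfg$pm_transition_hz >= cfg$fs / 2)
    stop("pm_edge_hz + pm_transition_hz must be below the Nyquist frequency")
  if (cfg$lp_order %% 2L != 0L || cfg$hp_order %% 2L != 0L)
    stop("FIR orders must be even so the group delay is an integer")
  if (cfg$pm_ripple <= 0 || cfg$pm_ripple >= 1)
    stop("pm_ripple must lie in (0, 1)")
  if (cfg$n_beats < 2L) stop("n_beats must be at least 2")
  structure(cfg, class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' The file may specify any subset of the `run_config()` fields; unspecified
#' fields keep their defaults. Entries passed via `overrides` (e.g. parsed
#' command-line flags) take precedence over the file.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @param overrides Named list of field overrides.
#' @return A `run_config`.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  vals <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("configuration file not found: ", path)
    vals <- yaml::read_yaml(path)
    if (!is.list(vals)) stop("configuration file must contain a YAML mapping")
  }
  vals[names(overrides)] <- overrides
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown configuration field(s): ", paste(bad, collapse = ", "))
  do.call(run_config, vals)
}

#' Read a PPG signal from a plain-text file
#'
#' Expects one numeric sample per row, optionally preceded by a single header
#' line of the form `fs=<value>`. The sampling rate must come from the
#' header, the `fs_override` argument, or `default_fs`; if none supplies it,
#' ingestion fails. Signals at rates other than `resample_to` are resampled
#' (cubic spline) to the canonical processing rate so that the fixed filter
#' orders keep their designed responses.
#'
#' @param path File path.
#' @param fs_override Sampling rate in Hz taking precedence over the header.
#' @param default_fs Fallback rate when neither header nor override gives one.
#' @param resample_to Canonical rate to resample to (default 1000 Hz); `NULL`
#'   keeps the native rate.
#' @return A `sampled_signal`.
#' @export
read_ppg_signal <- function(path, fs_override = NULL, default_fs = NULL,
                            resample_to = 1000) {
  if (!file.exists(path)) stop("signal file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("signal file is empty: ", path)
  fs <- NULL
  if (grepl("^\\s*fs\\s*=", lines[1L])) {
    fs <- suppressWarnings(as.numeric(sub("^\\s*fs\\s*=\\s*", "", lines[1L])))
    if (is.na(fs)) stop("unparseable fs header: ", lines[1L])
    lines <- lines[-1L]
    row_offset <- 1L
  } else row_offset <- 0L
  if (!is.null(fs_override)) fs <- fs_override
  if (is.null(fs)) fs <- default_fs
  if (is.null(fs))
    stop("sampling rate unknown: no fs header, no override, no default")
  x <- suppressWarnings(as.numeric(lines))
  bad <- which(is.na(x))
  if (length(bad))
    stop(sprintf("non-numeric sample in row %d: '%s'",
                 bad[1L] + row_offset, lines[bad[1L]]))
  sig <- sampled_signal(x, fs, label = basename(path))
  if (!is.null(resample_to) && !isTRUE(all.equal(fs, resample_to)))
    sig <- resample_signal(sig, resample_to)
  sig
}

#' Resample a signal to a new rate with a cubic spline
#'
#' @param x A `sampled_signal`.
#' @param fs_new Target rate in Hz.
#' @return A `sampled_signal` at `fs_new` spanning the same time interval.
#' @export
resample_signal <- function(x, fs_new) {
  stopifnot(inherits(x, "sampled_signal"))
  t_old <- signal_times(x)
  t_new <- seq(t_old[1L], t_old[length(t_old)], by = 1 / fs_new)
  f <- stats::splinefun(t_old, x$samples, method = "fmm")
  sampled_signal(f(t_new), fs_new, label = x$label, t0 = t_old[1L])
}

#' Write a wave-feature table to CSV
#'
#' Columns: `beat_index`, amplitudes `a`..`e`, times `t_a`..`t_e`,
#' normalized ratios and `agi`, plus the `ok` flag and `reason` for beats
#' where detection failed. Values round-trip at 15 significant digits.
#'
#' @param features A data frame as produced by [per_beat_features()] or
#'   [detect_waves()] (coerced with `as.data.frame`).
#' @param path Output file path.
#' @export
write_wave_features <- function(features, path) {
  features <- as.data.frame(features)
  if (!nrow(features)) stop("refusing to write an empty feature table")
  num <- vapply(features, is.numeric, logical(1L))
  out <- features
  out[num] <- lapply(features[num], function(col) {
    ifelse(is.na(col), "", sprintf("%.15g", col))
  })
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a wave-feature table written by [write_wave_features()]
#' @param path CSV path.
#' @return A data frame with numeric columns restored.
#' @export
read_wave_features <- function(path) {
  if (!file.exists(path)) stop("feature file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df
}

#' Read a cohort table
#'
#' Expected columns: `subject_id`, `age` (years), `group` (`healthy` or
#' `patient`); optional `agi` and `agi_sd`.
#'
#' @param path CSV path.
#' @return A validated data frame of cohort records.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_cohort(df)
}

#' Validate a cohort record table
#' @param df Data frame with at least `subject_id`, `age`, `group`.
#' @return The validated data frame (group as factor healthy/patient).
#' @export
validate_cohort <- function(df) {
  need <- c("subject_id", "age", "group")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("cohort table lacks column(s): ", paste(miss, collapse = ", "))
  if (any(!is.finite(df$age)) || any(df$age <= 0))
    stop("ages must be positive and finite")
  if (!all(df$group %in% c("healthy", "patient")))
    stop("group must be 'healthy' or 'patient'")
  if ("agi_sd" %in% names(df) && any(stats::na.omit(df$agi_sd) < 0))
    stop("agi_sd must be non-negative")
  df$group <- factor(df$group, levels = c("healthy", "patient"))
  df
}
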