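#' Dispersion of per-beat values about the averaged-waveform value
#'
#' \deqn{SD = \sqrt{\sum_i (x_a(i) - x_{avg})^2 / (n - 1)},}
#' the beat-to-beat standard deviation computed about the value measured on
#' the averaged waveform -- not about the sample mean. It reduces to the
#' ordinary (n-1)-denominator standard deviation when `x_avg` happens to
#' equal the sample mean.
#'
#' @param x_a Numeric vector of per-beat values (length >= 2).
#' @param x_avg Reference value from the averaged waveform.
#' @return Non-negative scalar.
#' @export
sd_about_reference <- function(x_a, x_avg) {
  x_a <- x_a[is.finite(x_a)]
  n <- length(x_a)
  if (n < 2L) stop("need at least 2 per-beat values")
  if (!is.finite(x_avg)) stop("`x_avg` must be finite")
  sqrt(sum((x_a - x_avg)^2) / (n - 1))
}

#' Group average of per-subject dispersions
#'
#' @param sds Numeric vector of per-subject standard deviations.
#' @return Their arithmetic mean.
#' @export
sd_group_average <- function(sds) {
  sds <- sds[is.finite(sds)]
  if (!length(sds)) stop("no finite per-subject standard deviations")
  mean(sds)
}

#' Number of harmonics passed by a low-pass edge
#'
#' Counts the integer multiples of the fundamental that lie strictly above
#' it and at or below the passband edge; on the normalized 1 s base the
#' fundamental sits at 1 Hz, so an edge of 6 Hz passes the fundamental plus
#' 5 higher harmonic components.
#'
#' @param edge_hz Passband edge in Hz.
#' @param fundamental_hz Fundamental frequency in Hz (default 1).
#' @return Integer count of higher harmonics passed.
#' @export
harmonics_passed <- function(edge_hz, fundamental_hz = 1) {
  if (edge_hz < fundamental_hz) stop("edge must be at least the fundamental")
  as.integer(floor(edge_hz / fundamental_hz) - 1L)
}

#' Edge-frequency optimization sweep
#'
#' Runs the full analysis once per subject and per candidate passband edge,
#' computes the per-subject dispersion of the ageing index, the normalized
#' amplitudes and the wave peak times (ms) about their averaged-waveform
#' values, and averages each dispersion over the group. Subjects failing
#' detection at some edge leave that cell missing; it is excluded from the
#' group average.
#'
#' @param signals List of `sampled_signal` recordings (one per subject).
#' @param grid Numeric vector of candidate edge frequencies in Hz.
#' @param config A [run_config()]; its `pm_edge_hz` is overridden per grid
#'   point.
#' @return A list of class `sweep_result`: `edge_hz`, `sd_avg` (data frame,
#'   one row per edge, one column per statistic), `per_subject` (array
#'   edge x subject x statistic), `argmin` (named vector: best edge per
#'   statistic), `failures` (data frame of skipped subject/edge cells).
#' @export
edge_frequency_sweep <- function(signals, grid = 4:14, config = run_config()) {
  if (!length(signals)) stop("no signals supplied")
  grid <- as.numeric(grid)
  if (is.unsorted(grid, strictly = TRUE)) stop("edge grid must be strictly increasing")
  stat_names <- c("agi", "b_over_a", "c_over_a", "d_over_a", "e_over_a",
                  "t_a_ms", "t_b_ms", "t_c_ms", "t_d_ms", "t_e_ms")
  per <- array(NA_real_,
               dim = c(length(grid), length(signals), length(stat_names)),
               dimnames = list(edge = as.character(grid), subject = NULL,
                               stat = stat_names))
  failures <- data.frame(subject = integer(0), edge_hz = numeric(0),
                         reason = character(0))
  # per-subject preprocessing is edge-independent: do it once
  for (si in seq_along(signals)) {
    pre <- tryCatch({
      ac <- bandpass_ppg(signals[[si]], config)
      derivative_set(ac, config)
    }, error = function(e) e)
    for (gi in seq_along(grid)) {
      cfg <- config
      cfg$pm_edge_hz <- grid[gi]
      res <- tryCatch({
        if (inherits(pre, "error")) stop(conditionMessage(pre))
        sweep_cell(pre, cfg)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        failures <- rbind(failures,
                          data.frame(subject = si, edge_hz = grid[gi],
                                     reason = conditionMessage(res)))
      } else {
        per[gi, si, ] <- res[stat_names]
      }
    }
  }
  sd_avg <- as.data.frame(apply(per, c(1, 3), function(v)
    if (all(is.na(v))) NA_real_ else sd_group_average(v)))
  sd_avg <- cbind(edge_hz = grid, sd_avg)
  rownames(sd_avg) <- NULL
  argmin <- vapply(stat_names, function(s) {
    v <- sd_avg[[s]]
    if (all(is.na(v))) NA_real_ else grid[which.min(v)]
  }, numeric(1L))
  structure(list(edge_hz = grid, sd_avg = sd_avg, per_subject = per,
                 argmin = argmin, failures = failures),
            class = "sweep_result")
}

# dispersions for one subject at one edge, starting from its derivative_set
sweep_cell <- function(ds, cfg) {
  pm <- design_pm_lowpass(cfg$pm_edge_hz, cfg$pm_transition_hz,
                          cfg$pm_ripple, cfg$fs)
  seg_all <- detect_recurrences(ds$ppg, cfg)
  C <- pm_context_samples(pm)
  ctx_ok <- vapply(seq_len(nrow(seg_all)), function(i) {
    pad <- ceiling(C * seg_all$duration_s[i] / 1000 * cfg$fs) + 8L
    seg_all$start[i] - pad >= 1L &&
      seg_all$end[i] + pad <= length(ds$ppg$samples)
  }, logical(1L))
  seg <- seg_all[ctx_ok, , drop = FALSE]
  if (nrow(seg) < cfg$n_beats)
    stop(sprintf("only %d beats with sufficient context, %d required",
                 nrow(seg), cfg$n_beats))
  seg <- utils::head(seg, cfg$n_beats)
  beats <- lapply(seq_len(nrow(seg)), function(i)
    normalize_recurrence(ds, seg[i, ], cfg, pm))
  avg <- align_and_average(beats)
  avg_feat <- detect_waves(avg, search_window_s = cfg$search_window_s,
                           search_pre_s = cfg$search_pre_s)
  beat_feat <- per_beat_features(beats,
                                 search_window_s = cfg$search_window_s,
                                 search_pre_s = cfg$search_pre_s)
  if (sum(beat_feat$ok) < 2L)
    stop("fewer than 2 beats with resolved waves")
  beat_dispersions(beat_feat, avg_feat)
}

#' Sweep report as a long-format data frame
#' @param sweep A `sweep_result`.
#' @return Data frame with columns `edge_hz`, `statistic`, `sd_avg`.
#' @export
sweep_report <- function(sweep) {
  stopifnot(inherits(sweep, "sweep_result"))
  stats <- setdiff(names(sweep$sd_avg), "edge_hz")
  do.call(rbind, lapply(stats, function(s)
    data.frame(edge_hz = sweep$sd_avg$edge_hz, statistic = s,
               sd_avg = sweep$sd_avg[[s]])))
}
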