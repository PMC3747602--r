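#' Sub-sample zero crossings of a sequence
#'
#' Every sign change is located by linear interpolation between the two
#' bracketing samples; samples that are exactly zero are reported once (a
#' run of zeros collapses to its first sample). Positions are 0-based
#' fractional sample indices.
#'
#' @param v Numeric vector, length >= 2.
#' @return Numeric vector of crossing positions (possibly empty).
#' @export
zero_crossings <- function(v) {
  n <- length(v)
  if (n < 2L) stop("need at least 2 samples")
  i <- seq_len(n - 1L)
  strict <- which(v[i] * v[i + 1L] < 0)
  pos <- (strict - 1) + v[strict] / (v[strict] - v[strict + 1L])
  zi <- which(v == 0)
  if (length(zi)) {
    zi <- zi[c(TRUE, diff(zi) > 1L)]      # collapse runs of exact zeros
    pos <- c(pos, zi - 1)
  }
  sort(unique(pos))
}

#' Ageing index from the five SDPPG wave amplitudes
#'
#' @param a,b,c,d,e Signed amplitudes of the systolic SDPPG waves.
#' @return `(b - c - d - e)/a`, dimensionless.
#' @export
agi <- function(a, b, c, d, e) {
  if (any(a == 0)) stop("wave 'a' amplitude must be nonzero")
  (b - c - d - e) / a
}

# Wave detection on a (tau, sdppg, d4) triple. tau is the time grid
# relative to the alignment reference, uniformly spaced. The window opens
# search_pre_s BEFORE the reference because the "a" wave (the curvature
# maximum low on the upstroke) typically precedes the 50% rising-front
# point. Returns a one-row data frame or signals an error describing how
# many waves were resolved.
detect_waves_core <- function(tau, sdppg, d4, search_window_s = 0.7,
                              search_pre_s = 0.2) {
  win <- which(tau >= -search_pre_s & tau <= search_window_s)
  if (length(win) < 8L)
    stop("waveform does not cover the systolic search window")
  tw <- tau[win]; sw <- sdppg[win]; dw <- d4[win]
  dt <- tw[2L] - tw[1L]
  cross <- zero_crossings(dw)             # 0-based fractional positions
  if (length(cross) < 2L)
    stop("wave detection failed: 0 of 5 waves resolved (too few fourth-derivative zero crossings)")
  want <- c(a = 1, b = -1, c = 1, d = -1, e = 1)
  idx0 <- seq_along(sw) - 1               # 0-based grid positions
  interval_points <- function(r)
    which(idx0 > cross[r] & idx0 < cross[r + 1L])
  local_extremum <- function(pts, sign) {
    if (!length(pts)) return(NA_integer_)
    vals <- sign * sw[pts]
    j <- pts[which.max(vals)]             # earliest wins ties
    if (j <= 1L || j >= length(sw)) return(NA_integer_)
    if (sign * sw[j] >= sign * sw[j - 1L] && sign * sw[j] >= sign * sw[j + 1L]) j
    else NA_integer_
  }
  # wave "a": first inter-crossing interval holding a positive interior
  # maximum of the SDPPG that reaches at least 20% of the window maximum
  # (so residual noise ripples ahead of the upstroke are never mistaken
  # for "a"; the true initial wave is always within a factor ~2 of the
  # dominant SDPPG excursion)
  a_floor <- 0.2 * max(sw)
  r_a <- NA_integer_
  for (r in seq_len(length(cross) - 1L)) {
    j <- local_extremum(interval_points(r), 1)
    if (!is.na(j) && sw[j] > 0 && sw[j] >= a_floor) { r_a <- r; break }
  }
  if (is.na(r_a))
    stop("wave detection failed: 0 of 5 waves resolved (no positive 'a' wave)")
  picks <- integer(5L); fallback <- logical(5L)
  for (wi in 1:5) {
    r <- r_a + wi - 1L
    if (r + 1L > length(cross))
      stop(sprintf("wave detection failed: %d of 5 waves resolved (ran out of zero crossings)",
                   wi - 1L))
    pts <- interval_points(r)
    j <- local_extremum(pts, want[wi])
    if (is.na(j)) {
      if (wi %in% c(1L, 2L))              # a and b must be true extrema
        stop(sprintf("wave detection failed: %d of 5 waves resolved (no '%s' extremum)",
                     wi - 1L, names(want)[wi]))
      if (!length(pts))
        stop(sprintf("wave detection failed: %d of 5 waves resolved (empty interval)",
                     wi - 1L))
      j <- pts[which.max(abs(dw[pts]))]   # place at the fourth-derivative extremum
      fallback[wi] <- TRUE
    }
    picks[wi] <- j
  }
  amp <- sw[picks]
  if (amp[1L] <= 0)
    stop("wave detection failed: 'a' wave amplitude is not positive")
  tt <- tw[picks]
  data.frame(a = amp[1L], b = amp[2L], c = amp[3L], d = amp[4L], e = amp[5L],
             t_a = tt[1L], t_b = tt[2L], t_c = tt[3L], t_d = tt[4L], t_e = tt[5L],
             b_over_a = amp[2L] / amp[1L], c_over_a = amp[3L] / amp[1L],
             d_over_a = amp[4L] / amp[1L], e_over_a = amp[5L] / amp[1L],
             agi = agi(amp[1L], amp[2L], amp[3L], amp[4L], amp[5L]),
             fallback_c = fallback[3L], fallback_d = fallback[4L],
             ok = TRUE, reason = "", stringsAsFactors = FALSE)
}

#' Detect the a--e waves on an averaged waveform set
#'
#' Zero crossings of the averaged fourth derivative partition the systolic
#' search window; wave "a" is the SDPPG maximum between the first crossing
#' pair holding a positive interior maximum, and waves b, c, d, e follow in
#' the successive intervals with alternating polarity (min, max, min, max).
#' Where the SDPPG has no interior extremum of the expected polarity
#' (flat/missing "c" or "d"), the wave is placed at the fourth-derivative
#' extremum of that interval. Amplitudes are read from the SDPPG at the
#' chosen grid times; normalized ratios and the ageing index are attached.
#'
#' @param avg An `averaged_waveform_set` from [align_and_average()].
#' @param search_window_s Systolic search window length in s after the
#'   alignment reference.
#' @param search_pre_s How far before the reference the window opens (s);
#'   the "a" wave sits low on the upstroke and precedes the 50% point.
#' @return One-row data frame with amplitudes `a`..`e`, times `t_a`..`t_e`
#'   (s, relative to the reference), ratios, `agi`, and fallback flags.
#' @export
detect_waves <- function(avg, search_window_s = 0.7, search_pre_s = 0.2) {
  stopifnot(inherits(avg, "averaged_waveform_set"))
  detect_waves_core(avg$tau, avg$sdppg_avg, avg$d4_avg, search_window_s,
                    search_pre_s)
}

#' Per-beat wave features from normalized recurrences
#'
#' Runs the wave detector on every normalized beat individually, each beat's
#' own fourth derivative guiding its detection. Beats where detection fails
#' produce a flagged row (`ok = FALSE` with the reason) rather than an
#' error.
#'
#' @param beats List of `normalized_beat` objects.
#' @param search_window_s Systolic search window in s after the reference.
#' @param search_pre_s Window opening before the reference (s).
#' @return Data frame with one row per beat (`beat_index` first).
#' @export
per_beat_features <- function(beats, search_window_s = 0.7,
                              search_pre_s = 0.2) {
  if (!length(beats)) stop("no beats supplied")
  grid0 <- (0:999) / 1000
  rows <- lapply(seq_along(beats), function(i) {
    b <- beats[[i]]
    row <- tryCatch({
      if (!is.finite(b$ref_time)) stop("no rising front found")
      detect_waves_core(grid0 - b$ref_time, b$sd2, b$d4, search_window_s,
                        search_pre_s)
    }, error = function(e) failed_feature_row(conditionMessage(e)))
    cbind(beat_index = i, row)
  })
  do.call(rbind, rows)
}

failed_feature_row <- function(reason) {
  data.frame(a = NA_real_, b = NA_real_, c = NA_real_, d = NA_real_,
             e = NA_real_, t_a = NA_real_, t_b = NA_real_, t_c = NA_real_,
             t_d = NA_real_, t_e = NA_real_, b_over_a = NA_real_,
             c_over_a = NA_real_, d_over_a = NA_real_, e_over_a = NA_real_,
             agi = NA_real_, fallback_c = NA, fallback_d = NA,
             ok = FALSE, reason = reason, stringsAsFactors = FALSE)
}

#' Simplified per-beat baseline analysis
#'
#' Reference mode for dispersion comparisons: band separation and smooth
#' differentiation only -- no time normalization, no equiripple filtering,
#' no ensemble averaging. Waves are detected on every raw beat from its own
#' fourth-derivative zero crossings, with the systolic search window scaled
#' by the beat duration.
#'
#' @param x A `sampled_signal` with the raw PPG at the canonical rate.
#' @param n_beats Number of beats to analyze.
#' @param config A [run_config()].
#' @return Data frame of per-beat features as in [per_beat_features()].
#' @export
baseline_per_beat <- function(x, n_beats = 15, config = run_config()) {
  ac <- bandpass_ppg(x, config)
  ds <- derivative_set(ac, config)
  seg <- segment_beats(ds$ppg, n_beats, config)
  fs <- ds$ppg$fs
  rows <- lapply(seq_len(nrow(seg)), function(i) {
    s <- seg[i, ]
    sl <- s$start:(s$end - 1L)
    p <- ds$ppg$samples[sl]
    row <- tryCatch({
      ref <- rising_front_reference(p)
      if (!is.finite(ref)) stop("no rising front found")
      tau <- (seq_along(sl) - 1) / fs - ref / fs
      detect_waves_core(tau, ds$sd2$samples[sl], ds$d4$samples[sl],
                        search_window_s = 0.7 * s$duration_s,
                        search_pre_s = 0.2 * s$duration_s)
    }, error = function(e) failed_feature_row(conditionMessage(e)))
    cbind(beat_index = i, row)
  })
  do.call(rbind, rows)
}
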