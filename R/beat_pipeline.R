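#' Detect cardiac recurrences (beats) in an AC PPG signal
#'
#' Foot-to-foot segmentation driven by the first derivative: steepest-rise
#' points are local maxima of the smooth-differentiated signal exceeding
#' half the median prominent-peak height, with a 0.3 s refractory period;
#' each beat's foot is the signal minimum in the 0.35 s window preceding a
#' rise point. Consecutive feet delimit one recurrence; durations outside
#' the physiological 0.3--2 s range are discarded.
#'
#' @param ac A `sampled_signal` with the AC PPG.
#' @param config A [run_config()].
#' @return Data frame with one row per detected recurrence: `start`, `end`
#'   (half-open sample indices into `ac`), `duration_s`.
#' @export
detect_recurrences <- function(ac, config = run_config()) {
  stopifnot(inherits(ac, "sampled_signal"))
  fs <- ac$fs
  kernel <- snrd_kernel(config$snrd_length, step = 1 / fs)
  M <- (kernel$length - 1L) / 2L
  d1 <- snrd_differentiate(ac, 1, kernel)$samples
  n1 <- length(d1)
  if (n1 < 3L) stop("signal too short for beat detection")
  up <- which(d1[2:(n1 - 1L)] > d1[1:(n1 - 2L)] &
              d1[2:(n1 - 1L)] >= d1[3:n1] &
              d1[2:(n1 - 1L)] > 0) + 1L
  if (!length(up)) stop("no beats detected: first derivative has no positive peaks")
  hts <- d1[up]
  prominent <- hts[hts > 0.5 * max(hts)]
  thr <- 0.5 * stats::median(prominent)
  cand <- up[hts > thr]
  refr <- round(0.3 * fs)
  # greedy refractory selection, tallest first, deterministic tie-break on index
  ord <- cand[order(-d1[cand], cand)]
  keep <- integer(0)
  for (i in ord) if (!length(keep) || min(abs(keep - i)) > refr) keep <- c(keep, i)
  rises <- sort(keep) + M                 # map onto the ac grid
  # foot: minimum in the 0.35 s window before each rise point
  w <- round(0.35 * fs)
  feet <- vapply(rises, function(r) {
    lo <- max(1L, r - w)
    as.integer(lo + which.min(ac$samples[lo:r]) - 1L)
  }, integer(1L))
  feet <- unique(feet)
  if (length(feet) < 2L)
    stop("no beats detected: fewer than two pulse feet found")
  # inter-beat-interval correction: a spurious intra-beat rise point (e.g.
  # a noise spike on the dicrotic limb) splits one beat into two short
  # fragments; drop the shared foot when two adjacent intervals are jointly
  # about one median beat long and one of them is clearly too short
  for (pass in 1:4) {
    d <- diff(feet) / fs
    if (length(d) < 3L) break
    med <- stats::median(d)
    drop <- integer(0)
    i <- 1L
    while (i < length(d)) {
      if (min(d[i], d[i + 1L]) < 0.7 * med &&
          d[i] + d[i + 1L] <= 1.4 * med) {
        drop <- c(drop, i + 1L)   # the foot between the two fragments
        i <- i + 2L
      } else i <- i + 1L
    }
    if (!length(drop)) break
    feet <- feet[-drop]
  }
  seg <- data.frame(start = feet[-length(feet)], end = feet[-1L])
  seg$duration_s <- (seg$end - seg$start) / fs
  seg <- seg[seg$duration_s >= 0.3 & seg$duration_s <= 2, , drop = FALSE]
  rownames(seg) <- NULL
  seg
}

#' Select the first `n_beats` recurrences of a recording
#'
#' @inheritParams detect_recurrences
#' @param n_beats Number of consecutive beats required.
#' @param min_context_s Seconds of signal that must surround each beat (on
#'   both sides) for the later per-recurrence filtering; beats without that
#'   context are skipped.
#' @return Data frame of `n_beats` rows as in [detect_recurrences()].
#' @export
segment_beats <- function(ac, n_beats = 15, config = run_config(),
                          min_context_s = 0) {
  seg <- detect_recurrences(ac, config)
  if (min_context_s > 0) {
    pad <- ceiling(min_context_s * ac$fs)
    ok <- seg$start - pad >= 1L & seg$end + pad <= length(ac$samples)
    seg <- seg[ok, , drop = FALSE]
  }
  if (nrow(seg) < n_beats)
    stop(sprintf("only %d usable beats detected, %d required", nrow(seg), n_beats))
  utils::head(seg, n_beats)
}

# normalized-grid context (samples at 1 kHz) needed around the 1 s beat so
# the equiripple filter output fully supports it
pm_context_samples <- function(pm, pad = 160L) {
  ceiling(length(pm$h) / 2) + pad
}

#' Normalize one recurrence to the 1 s base and filter it
#'
#' A window of each channel (the beat plus surrounding context) is resampled
#' by cubic spline so that the recurrence spans exactly 1 s -- placing the
#' pulse fundamental at 1 Hz and its harmonics at integer Hz -- then
#' filtered with the verified equiripple low-pass and compensated for the
#' filter's group delay, and the 1 s segment is extracted. The second and
#' fourth derivatives are resampled and filtered identically; because they
#' were differentiated before resampling they carry a `duration^k` scale
#' factor relative to derivatives of the normalized pulse, which cancels in
#' all normalized ratios.
#'
#' @param ds A [derivative_set()].
#' @param segment One-row data frame (or list) with `start`, `end`,
#'   `duration_s` as from [detect_recurrences()].
#' @param config A [run_config()]; `pm_edge_hz`, `pm_transition_hz` and
#'   `pm_ripple` specify the filter.
#' @param pm Optional pre-built design from [design_pm_lowpass()].
#' @return An object of class `normalized_beat`: `ppg`, `sd2`, `d4`
#'   (numeric, 1000 samples at 1 kHz), `ref_time` (s, the 50% rising-front
#'   crossing, `NA` if not found), `original_duration` (s).
#' @export
normalize_recurrence <- function(ds, segment, config = run_config(), pm = NULL) {
  stopifnot(inherits(ds, "derivative_set"))
  if (is.null(pm))
    pm <- design_pm_lowpass(config$pm_edge_hz, config$pm_transition_hz,
                            config$pm_ripple, config$fs)
  fs <- ds$ppg$fs
  d <- segment$duration_s
  C <- pm_context_samples(pm)
  t_start <- ds$ppg$t0 + (segment$start - 1) / fs
  jj <- (-C):(999L + C)                     # normalized 1 kHz grid
  t_eval <- t_start + jj / 1000 * d         # original-time positions
  t_lo <- ds$ppg$t0
  t_hi <- ds$ppg$t0 + (length(ds$ppg$samples) - 1) / fs
  if (t_eval[1L] < t_lo || t_eval[length(t_eval)] > t_hi)
    stop(sprintf(
      "insufficient context around beat at %.2f s: need %.2f s on each side",
      t_start, C * d / 1000))
  i1 <- max(1L, floor((t_eval[1L] - t_lo) * fs) - 2L)
  i2 <- min(length(ds$ppg$samples), ceiling((t_eval[length(t_eval)] - t_lo) * fs) + 4L)
  idx <- i1:i2
  tt <- t_lo + (idx - 1) / fs
  chan <- lapply(list(ppg = ds$ppg, sd2 = ds$sd2, d4 = ds$d4), function(sg) {
    res <- stats::spline(tt, sg$samples[idx], xout = t_eval, method = "fmm")$y
    out <- pm_apply(res, pm$h)
    # output sample i corresponds to normalized index jj[i + out$offset]
    first <- 1L + C - out$offset            # position of j = 0
    if (first < 1L || first + 999L > length(out$y))
      stop("internal error: filtered window does not cover the beat")
    out$y[first:(first + 999L)]
  })
  ref <- rising_front_reference(chan$ppg) / 1000
  structure(list(ppg = chan$ppg, sd2 = chan$sd2, d4 = chan$d4,
                 ref_time = ref, original_duration = d),
            class = "normalized_beat")
}

# sub-sample index (0-based) of the first upward crossing of
# foot + 0.5*(systolic peak - foot); NA when no rising front is found
rising_front_reference <- function(p) {
  peak <- which.max(p)
  if (peak < 3L) return(NA_real_)
  foot <- which.min(p[1:peak])
  if (foot >= peak) return(NA_real_)
  level <- p[foot] + 0.5 * (p[peak] - p[foot])
  for (i in foot:(peak - 1L)) {
    if (p[i] <= level && p[i + 1L] > level) {
      frac <- (level - p[i]) / (p[i + 1L] - p[i])
      return(i - 1 + frac)
    }
  }
  NA_real_
}

#' Align normalized recurrences at the 50% rising front and average
#'
#' Each beat is shifted (by spline interpolation, sub-sample accurate) so
#' that its rising-front reference time coincides with time 0; the PPG,
#' SDPPG and fourth-derivative channels are then averaged pointwise over
#' the intersection of all aligned supports. Beats whose rising front could
#' not be located are rejected (counted in `n_rejected`).
#'
#' @param beats List of `normalized_beat` objects.
#' @return An object of class `averaged_waveform_set`: `tau` (time grid in
#'   s relative to the reference point), `ppg_avg`, `sdppg_avg`, `d4_avg`,
#'   `n_beats`, `n_rejected`.
#' @export
align_and_average <- function(beats) {
  ok <- vapply(beats, function(b) is.finite(b$ref_time), logical(1L))
  rejected <- sum(!ok)
  beats <- beats[ok]
  if (length(beats) < 2L)
    stop(sprintf("need at least 2 alignable beats, have %d (%d rejected)",
                 length(beats), rejected))
  refs <- vapply(beats, `[[`, numeric(1L), "ref_time")
  j_lo <- ceiling(max(-refs) * 1000)
  j_hi <- floor(min(1 - refs) * 1000) - 2L
  if (j_hi <= j_lo) stop("aligned beats share no common support")
  tau <- (j_lo:j_hi) / 1000
  grid0 <- (0:999) / 1000
  acc <- list(ppg = 0, sd2 = 0, d4 = 0)
  for (b in beats) {
    x <- tau + b$ref_time
    acc$ppg <- acc$ppg + stats::spline(grid0, b$ppg, xout = x, method = "fmm")$y
    acc$sd2 <- acc$sd2 + stats::spline(grid0, b$sd2, xout = x, method = "fmm")$y
    acc$d4 <- acc$d4 + stats::spline(grid0, b$d4, xout = x, method = "fmm")$y
  }
  m <- length(beats)
  structure(list(tau = tau, ppg_avg = acc$ppg / m, sdppg_avg = acc$sd2 / m,
                 d4_avg = acc$d4 / m, n_beats = m, n_rejected = rejected),
            class = "averaged_waveform_set")
}

#' Run the full SDPPG analysis on one recording
#'
#' Band separation, smooth differentiation, beat segmentation, per-beat
#' time normalization and equiripple filtering, rising-front alignment,
#' ensemble averaging, and a--e wave detection on both the averaged
#' waveform and every individual beat, plus the beat-to-beat dispersion of
#' each statistic about its averaged-waveform value.
#'
#' @param x A `sampled_signal` holding the raw PPG at the canonical rate.
#' @param config A [run_config()].
#' @return A list of class `sdppg_analysis` with elements `avg_features`
#'   (one-row data frame), `beat_features` (per-beat data frame), `sds`
#'   (named vector of dispersions about the averaged-waveform values),
#'   `average` (the `averaged_waveform_set`), `beats`, `segments`, `config`.
#' @export
analyze_ppg <- function(x, config = run_config()) {
  ac <- bandpass_ppg(x, config)
  ds <- derivative_set(ac, config)
  pm <- design_pm_lowpass(config$pm_edge_hz, config$pm_transition_hz,
                          config$pm_ripple, config$fs)
  seg_all <- detect_recurrences(ds$ppg, config)
  C <- pm_context_samples(pm)
  ctx_ok <- vapply(seq_len(nrow(seg_all)), function(i) {
    d <- seg_all$duration_s[i]
    pad <- ceiling(C * d / 1000 * config$fs) + 8L
    seg_all$start[i] - pad >= 1L && seg_all$end[i] + pad <= length(ds$ppg$samples)
  }, logical(1L))
  seg <- seg_all[ctx_ok, , drop = FALSE]
  if (nrow(seg) < config$n_beats)
    stop(sprintf("only %d beats with sufficient context, %d required",
                 nrow(seg), config$n_beats))
  seg <- utils::head(seg, config$n_beats)
  beats <- lapply(seq_len(nrow(seg)), function(i)
    normalize_recurrence(ds, seg[i, ], config, pm))
  avg <- align_and_average(beats)
  avg_feat <- detect_waves(avg, search_window_s = config$search_window_s,
                           search_pre_s = config$search_pre_s)
  beat_feat <- per_beat_features(beats,
                                 search_window_s = config$search_window_s,
                                 search_pre_s = config$search_pre_s)
  sds <- beat_dispersions(beat_feat, avg_feat)
  structure(list(avg_features = avg_feat, beat_features = beat_feat,
                 sds = sds, average = avg, beats = beats, segments = seg,
                 config = config),
            class = "sdppg_analysis")
}

# Eq.-style dispersions of every per-beat statistic about its
# averaged-waveform value; times are reported in ms
beat_dispersions <- function(beat_feat, avg_feat) {
  stats_amp <- c("agi", "b_over_a", "c_over_a", "d_over_a", "e_over_a")
  stats_t <- c("t_a", "t_b", "t_c", "t_d", "t_e")
  ok <- beat_feat$ok
  out <- c(
    vapply(stats_amp, function(s)
      if (sum(ok) >= 2) sd_about_reference(beat_feat[[s]][ok], avg_feat[[s]])
      else NA_real_, numeric(1L)),
    vapply(stats_t, function(s)
      if (sum(ok) >= 2)
        sd_about_reference(1000 * beat_feat[[s]][ok], 1000 * avg_feat[[s]])
      else NA_real_, numeric(1L)))
  names(out) <- c(stats_amp, paste0(stats_t, "_ms"))
  out
}
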