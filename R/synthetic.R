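# Stiffness endpoints of the Gaussian-sum beat family. Interpolating the
# component table from `young` to `old` morphs the waveform from a wavy,
# compliant pulse (deep renormalized b trough, pronounced dicrotic limb,
# strongly negative ageing index) towards the stiffer, more triangular
# shape seen at higher vascular age (shallower b, deeper d, ageing index
# approaching zero and above). Endpoints were chosen so the clean-template
# ageing index is strictly monotone in the stiffness parameter and spans
# roughly [-1.94, 0.60], containing the physiological range with margin.
.template_young <- list(A = c(1, 0.3075, 0.0875),
                        mu = c(0.167, 0.29625, 0.62725),
                        sigma = c(0.07475, 0.0430, 0.13375))
.template_old <- list(A = c(1, 0.8190, 0.1650),
                      mu = c(0.1918, 0.2947, 0.5389),
                      sigma = c(0.0887, 0.0616, 0.1167))

#' Gaussian-sum beat template
#'
#' One cardiac recurrence modelled as a periodized sum of Gaussian
#' components (main systolic upstroke, late-systolic shoulder, dicrotic
#' wave), represented by its Fourier series truncated at `n_harmonics`
#' multiples of the pulse fundamental. The truncation makes the clean
#' template exactly band-limited on the normalized 1 s base, so a low-pass
#' whose passband covers all `n_harmonics` components is transparent to it.
#' The phase origin is shifted so that phase 0 is the waveform minimum (the
#' diastolic foot). The template's second derivative exhibits the five
#' alternating systolic waves a--e; this is verified at construction.
#'
#' @param stiffness Real in \[0, 1\] morphing the wave depths from
#'   "compliant" (0) to "stiff" (1); the clean-template ageing index is
#'   strictly increasing in it.
#' @param n_harmonics Number of Fourier harmonics retained (default 6, the
#'   minimal content that forms all five waves).
#' @param validate Check the a--e extremum pattern at construction.
#' @return Object of class `beat_template` with the complex Fourier
#'   coefficients (`coef`, harmonics 1..n), `stiffness`, `n_harmonics`,
#'   the component table, and (if validated) `features`.
#' @export
beat_template <- function(stiffness = 0.5, n_harmonics = 6, validate = TRUE) {
  if (!is.finite(stiffness) || stiffness < 0 || stiffness > 1)
    stop("`stiffness` must lie in [0, 1]")
  comp <- data.frame(
    A = (1 - stiffness) * .template_young$A + stiffness * .template_old$A,
    mu = (1 - stiffness) * .template_young$mu + stiffness * .template_old$mu,
    sigma = (1 - stiffness) * .template_young$sigma + stiffness * .template_old$sigma)
  n <- seq_len(n_harmonics)
  cf <- vapply(n, function(k)
    sum(comp$A * comp$sigma * sqrt(2 * pi) *
        exp(-2 * pi^2 * comp$sigma^2 * k^2) * exp(-2i * pi * k * comp$mu)),
    complex(1L))
  tpl <- structure(list(coef = cf, n_harmonics = n_harmonics,
                        stiffness = stiffness, components = comp),
                   class = "beat_template")
  # shift the phase origin to the diastolic foot (waveform minimum)
  ph <- seq(0, 1 - 1e-4, by = 1e-4)
  t_min <- ph[which.min(template_eval(tpl, ph))]
  tpl$coef <- cf * exp(2i * pi * n * t_min)
  if (validate) {
    feats <- template_features(tpl)
    if (any(c(feats$fallback_c, feats$fallback_d)))
      stop("template fails the a-e extremum pattern: c or d is not a true extremum")
    tpl$features <- feats
  }
  tpl
}

#' Evaluate a beat template (or a derivative) at given phases
#'
#' @param template A `beat_template`.
#' @param phase Phase values (period 1; any real, reduced mod 1).
#' @param deriv Derivative order (0, 1, 2, 4, ...) with respect to phase.
#' @return Numeric vector. The DC term is omitted (irrelevant after band
#'   separation).
#' @export
template_eval <- function(template, phase, deriv = 0) {
  n <- seq_len(template$n_harmonics)
  out <- numeric(length(phase))
  for (k in n) {
    fac <- (2i * pi * k)^deriv
    out <- out + 2 * Re(fac * template$coef[k] * exp(2i * pi * k * phase))
  }
  out
}

#' Ground-truth wave features of a clean template
#'
#' Detects the a--e waves on the analytic second and fourth derivatives of
#' the band-limited template at high phase resolution, using the same
#' fourth-derivative zero-crossing rule as the signal pipeline. Times are
#' phases on the normalized base (foot at 0).
#'
#' @param template A `beat_template`.
#' @param dt Phase resolution (default 1e-4).
#' @return One-row data frame as from [detect_waves()].
#' @export
template_features <- function(template, dt = 1e-4) {
  tau <- seq(0.02, 0.9, by = dt)
  sd2 <- template_eval(template, tau, 2)
  d4 <- template_eval(template, tau, 4)
  detect_waves_core(tau, sd2, d4, search_window_s = 0.9, search_pre_s = 0)
}

#' Clean-template ageing index as a function of stiffness
#' @param stiffness Stiffness parameter in \[0, 1\].
#' @param n_harmonics Harmonics retained.
#' @return The ageing index of the clean template.
#' @export
template_agi <- function(stiffness, n_harmonics = 6) {
  beat_template(stiffness, n_harmonics, validate = TRUE)$features$agi
}

# memoized dense grid of the (strictly monotone) stiffness -> AGI map,
# one per harmonic count
.agi_grid_cache <- new.env(parent = emptyenv())

agi_grid <- function(n_harmonics) {
  key <- as.character(n_harmonics)
  if (is.null(.agi_grid_cache[[key]])) {
    s <- seq(0, 1, by = 0.01)
    v <- vapply(s, template_agi, numeric(1L), n_harmonics = n_harmonics)
    if (any(diff(v) <= 0))
      stop("template AGI is not strictly monotone in stiffness")
    .agi_grid_cache[[key]] <- list(s = s, agi = v)
  }
  .agi_grid_cache[[key]]
}

#' Invert the stiffness--AGI map
#'
#' Finds the stiffness parameter whose clean-template ageing index equals
#' `target`, by interpolating the inverse of a dense pre-tabulated grid of
#' the strictly monotone stiffness-to-AGI map (accurate to well below
#' 0.01 in AGI).
#'
#' @param target Desired ageing index.
#' @param n_harmonics Harmonics retained.
#' @return Stiffness in \[0, 1\].
#' @export
stiffness_for_agi <- function(target, n_harmonics = 6) {
  g <- agi_grid(n_harmonics)
  lo <- g$agi[1L]; hi <- g$agi[length(g$agi)]
  if (target < lo || target > hi)
    stop(sprintf("target AGI %.3f outside the attainable range [%.3f, %.3f]",
                 target, lo, hi))
  stats::approx(g$agi, g$s, xout = target, ties = "ordered")$y
}

#' Specification of one synthetic PPG recording
#'
#' Defaults emulate a one-minute resting finger-PPG recording at the
#' canonical 1 kHz rate: about 70 beats of 0.9 s mean period with 3%
#' beat-to-beat period jitter, respiratory baseline drift near 0.2 Hz at
#' 30% of the AC swing, broadband noise at 2% of the AC RMS, and a large
#' DC offset as delivered by a transmission-mode sensor.
#'
#' @param n_beats Number of beats synthesized.
#' @param mean_period_s Mean beat period (s).
#' @param period_jitter Fractional SD of the beat period.
#' @param drift_amplitude Baseline drift amplitude relative to the AC
#'   peak-to-peak swing.
#' @param drift_hz Drift frequency (Hz).
#' @param noise_sd White-noise SD relative to the clean AC RMS.
#' @param powerline_hz Powerline frequency (0 disables).
#' @param powerline_amp Powerline amplitude relative to the AC RMS.
#' @param dc_level DC offset in template units.
#' @param fs Sampling rate (Hz).
#' @param seed Integer seed fixing the recording bit-for-bit.
#' @return Object of class `recording_spec` (named list).
#' @export
recording_spec <- function(n_beats = 70, mean_period_s = 0.9,
                           period_jitter = 0.03, drift_amplitude = 0.3,
                           drift_hz = 0.2, noise_sd = 0.02,
                           powerline_hz = 0, powerline_amp = 0.01,
                           dc_level = 10, fs = 1000, seed = 1) {
  spec <- list(n_beats = as.integer(n_beats), mean_period_s = mean_period_s,
               period_jitter = period_jitter,
               drift_amplitude = drift_amplitude, drift_hz = drift_hz,
               noise_sd = noise_sd, powerline_hz = powerline_hz,
               powerline_amp = powerline_amp, dc_level = dc_level,
               fs = fs, seed = as.integer(seed))
  if (spec$n_beats < 1L) stop("n_beats must be >= 1")
  if (spec$mean_period_s < 0.3 || spec$mean_period_s > 2)
    stop("mean_period_s must lie in the physiological range [0.3, 2] s")
  if (spec$period_jitter < 0 || spec$noise_sd < 0 || spec$drift_amplitude < 0)
    stop("jitter, noise and drift amplitudes must be non-negative")
  structure(spec, class = "recording_spec")
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Generate an annotated synthetic PPG recording
#'
#' Concatenates period-jittered copies of the clean beat template, adds
#' sinusoidal baseline drift, white broadband noise and (optionally) a
#' powerline component, and returns the signal together with ground-truth
#' annotations: beat onsets/periods and the clean per-beat wave times and
#' amplitudes on the normalized base, which are identical for every beat
#' up to the known time scaling.
#'
#' @param template A [beat_template()].
#' @param spec A [recording_spec()].
#' @return Object of class `ppg_recording`: `signal` (a `sampled_signal`),
#'   `annotations` (list: `beats` data frame with onsets, periods and
#'   global wave times; `features` the clean template features; `agi` the
#'   true ageing index), `template`, `spec`.
#' @export
generate_recording <- function(template, spec = recording_spec()) {
  stopifnot(inherits(template, "beat_template"), inherits(spec, "recording_spec"))
  feats <- if (!is.null(template$features)) template$features
           else template_features(template)
  with_seed(spec$seed, {
    z <- pmin(3, pmax(-3, stats::rnorm(spec$n_beats)))
    periods <- spec$mean_period_s * (1 + spec$period_jitter * z)
    onsets <- c(0, cumsum(periods))
    total <- onsets[spec$n_beats + 1L]
    t <- seq(0, total - 1 / spec$fs, by = 1 / spec$fs)
    clean <- numeric(length(t))
    bi <- findInterval(t, onsets, rightmost.closed = FALSE)
    bi[bi > spec$n_beats] <- spec$n_beats
    for (i in seq_len(spec$n_beats)) {
      m <- bi == i
      clean[m] <- template_eval(template, (t[m] - onsets[i]) / periods[i])
    }
    swing <- diff(range(clean))
    rms <- stats::sd(clean)
    drift_phase <- stats::runif(1, 0, 2 * pi)
    x <- clean + spec$dc_level +
      spec$drift_amplitude * swing * sin(2 * pi * spec$drift_hz * t + drift_phase) +
      spec$noise_sd * rms * stats::rnorm(length(t))
    if (spec$powerline_hz > 0)
      x <- x + spec$powerline_amp * rms * sin(2 * pi * spec$powerline_hz * t)
    beats <- data.frame(beat_index = seq_len(spec$n_beats),
                        onset_s = onsets[-length(onsets)], period_s = periods)
    for (w in c("a", "b", "c", "d", "e"))
      beats[[paste0("t_", w, "_global")]] <-
        beats$onset_s + feats[[paste0("t_", w)]] * beats$period_s
    structure(list(signal = sampled_signal(x, spec$fs, label = "synthetic PPG"),
                   annotations = list(beats = beats, features = feats,
                                      agi = feats$agi),
                   template = template, spec = spec),
              class = "ppg_recording")
  })
}

#' Generate a synthetic cohort with a linear AGI--age ground truth
#'
#' Ages are drawn uniformly per group; each subject's target ageing index
#' is `slope * age + intercept` plus Gaussian residual noise, offset upward
#' for patients; the stiffness parameter is then inverted numerically so
#' the subject's clean template attains the target. Recording seeds are
#' derived deterministically from `seed`.
#'
#' @param n_healthy,n_patient Group sizes.
#' @param age_range_healthy,age_range_patient Age ranges in years.
#' @param slope,intercept Linear model of AGI on age.
#' @param residual_sd SD of the AGI residual about the line.
#' @param patient_offset Upward AGI shift of the patient group.
#' @param seed Integer seed.
#' @param n_harmonics Template harmonics.
#' @param spec_args Named list of overrides passed to [recording_spec()]
#'   for every subject.
#' @param build_templates Build the per-subject beat templates (set `FALSE`
#'   when only the ground-truth records are needed, e.g. for statistical
#'   simulations that never synthesize signals).
#' @return Object of class `ppg_cohort`: `records` (data frame:
#'   `subject_id`, `age`, `group`, `agi` (ground truth), `stiffness`),
#'   `templates` (list), `specs` (list of `recording_spec`).
#' @export
generate_cohort <- function(n_healthy = 21, n_patient = 20,
                            age_range_healthy = c(21, 66),
                            age_range_patient = c(27, 66),
                            slope = 0.019, intercept = -1.556,
                            residual_sd = 0.126, patient_offset = 0.359,
                            seed = 1, n_harmonics = 6, spec_args = list(),
                            build_templates = TRUE) {
  if (n_healthy < 1L) stop("need at least one healthy subject")
  if (n_patient < 0L) stop("n_patient must be >= 0")
  g <- agi_grid(n_harmonics)
  lo <- g$agi[1L]; hi <- g$agi[length(g$agi)]
  with_seed(seed, {
    n <- n_healthy + n_patient
    group <- c(rep("healthy", n_healthy), rep("patient", n_patient))
    age <- c(stats::runif(n_healthy, age_range_healthy[1], age_range_healthy[2]),
             if (n_patient > 0)
               stats::runif(n_patient, age_range_patient[1], age_range_patient[2]))
    target <- slope * age + intercept + stats::rnorm(n, 0, residual_sd) +
      ifelse(group == "patient", patient_offset, 0)
    if (any(target < lo | target > hi))
      stop(sprintf(
        "target AGI outside the template family's attainable range [%.3f, %.3f]",
        lo, hi))
    stiffness <- vapply(target, stiffness_for_agi, numeric(1L),
                        n_harmonics = n_harmonics)
    records <- data.frame(
      subject_id = sprintf("S%02d", seq_len(n)),
      age = age, group = group, agi = target, stiffness = stiffness,
      stringsAsFactors = FALSE)
    templates <- if (build_templates)
      lapply(stiffness, beat_template, n_harmonics = n_harmonics) else NULL
    base_seed <- (abs(seed) %% 1000000L) * 1000L
    specs <- lapply(seq_len(n), function(i)
      do.call(recording_spec, c(list(seed = base_seed + i), spec_args)))
    structure(list(records = validate_cohort(records), templates = templates,
                   specs = specs),
              class = "ppg_cohort")
  })
}

#' Write a recording and its annotations to plain-text files
#'
#' The signal goes to `<path>.csv` (one sample per row with an `fs=` header,
#' readable by [read_ppg_signal()]); the beat annotations go to
#' `<path>_annotations.csv`.
#'
#' @param rec A `ppg_recording`.
#' @param path Output path prefix.
#' @return Invisibly, the two file paths.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "ppg_recording"))
  sig_path <- paste0(path, ".csv")
  ann_path <- paste0(path, "_annotations.csv")
  con <- file(sig_path, "w")
  writeLines(sprintf("fs=%g", rec$signal$fs), con)
  writeLines(sprintf("%.10g", rec$signal$samples), con)
  close(con)
  utils::write.csv(rec$annotations$beats, ann_path, row.names = FALSE)
  invisible(c(signal = sig_path, annotations = ann_path))
}
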