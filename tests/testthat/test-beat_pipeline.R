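test_that("clean periodic beats segment into equal foot-to-foot recurrences", {
  rec <- generate_recording(beat_template(0.4),
                            recording_spec(n_beats = 20, mean_period_s = 0.8,
                                           period_jitter = 0, noise_sd = 0,
                                           drift_amplitude = 0, seed = 1))
  ac <- bandpass_ppg(rec$signal, run_config())
  seg <- segment_beats(ac, n_beats = 10, run_config())
  expect_equal(nrow(seg), 10)
  expect_true(all(abs(seg$duration_s - 0.8) <= 0.005))
})

test_that("jittered beat durations match the generator's ground truth within 10 ms", {
  rec <- generate_recording(beat_template(0.5),
                            recording_spec(n_beats = 25, period_jitter = 0.05,
                                           noise_sd = 0, seed = 9))
  ac <- bandpass_ppg(rec$signal, run_config())
  seg <- detect_recurrences(ac, run_config())
  ann <- rec$annotations$beats
  # match each detected beat to the annotated beat with the closest onset
  t_start <- ac$t0 + (seg$start - 1) / ac$fs
  for (i in seq_len(nrow(seg))) {
    j <- which.min(abs(ann$onset_s - t_start[i]))
    expect_lt(abs(seg$duration_s[i] - ann$period_s[j]), 0.010)
  }
})

test_that("flat or beat-free signals are rejected with a count", {
  expect_error(detect_recurrences(sampled_signal(rep(0, 8000), 1000)),
               "no beats")
  rec <- generate_recording(beat_template(0.4),
                            recording_spec(n_beats = 20, seed = 2))
  ac <- bandpass_ppg(rec$signal, run_config())
  expect_error(segment_beats(ac, n_beats = 100, run_config()), "only \\d+")
})

test_that("time normalization yields exactly 1000 samples and suppresses out-of-band content", {
  ana <- clean_analysis()
  b <- ana$beats[[1]]
  expect_length(b$ppg, 1000)
  expect_length(b$sd2, 1000)
  expect_length(b$d4, 1000)
  expect_true(b$ref_time > 0 && b$ref_time < 1)
  # after normalization the fundamental sits at 1 Hz: projections onto
  # integer-Hz harmonics recover the template; content above the stopband
  # edge (>= 7 Hz) is attenuated below the 0.001 ripple
  g <- (0:999) / 1000
  amp <- function(x, f) 2 * Mod(mean(x * exp(-2i * pi * f * g)))
  a1 <- amp(b$ppg, 1)
  expect_gt(a1, 0)
  for (f in 8:12) expect_lt(amp(b$ppg, f), 0.002 * a1)
})

test_that("an exactly 1 s recurrence passes through resampling unchanged", {
  rec <- generate_recording(beat_template(0.4),
                            recording_spec(n_beats = 16, mean_period_s = 1.0,
                                           period_jitter = 0, noise_sd = 0,
                                           drift_amplitude = 0, seed = 4))
  ds <- derivative_set(bandpass_ppg(rec$signal, run_config()), run_config())
  seg <- detect_recurrences(ds$ppg, run_config())
  seg <- seg[abs(seg$duration_s - 1) < 1e-9, , drop = FALSE][3, ]
  nb <- normalize_recurrence(ds, seg, run_config())
  # reference: PM-filter the raw samples directly (no resampling step)
  pm <- design_pm_lowpass(6, 1, 0.001, 1000)
  C <- sdppg:::pm_context_samples(pm)
  idx <- (seg$start - C):(seg$start + 999 + C)
  out <- sdppg:::pm_apply(ds$ppg$samples[idx], pm$h)
  first <- 1 + C - out$offset
  direct <- out$y[first:(first + 999)]
  expect_lt(max(abs(nb$ppg - direct)) / diff(range(direct)), 1e-6)
})

test_that("alignment uses the mid-rise point and averaging preserves identical beats", {
  # closed form: a pure ramp crosses its 50% level at the midpoint
  ramp <- seq(0, 1, length.out = 101)
  expect_equal(sdppg:::rising_front_reference(ramp), 50, tolerance = 1e-9)

  ana <- clean_analysis()
  avg <- ana$average
  expect_gte(avg$n_beats, 2)
  # identical clean beats: the average equals any single aligned beat
  b <- ana$beats[[5]]
  g <- (0:999) / 1000
  bs <- stats::spline(g, b$sd2, xout = avg$tau + b$ref_time, method = "fmm")$y
  expect_lt(max(abs(avg$sdppg_avg - bs)) / diff(range(bs)), 1e-3)
  expect_error(align_and_average(ana$beats[1]), "at least 2")
})

test_that("averaging jittered noisy beats shrinks the high-frequency residual", {
  rec <- generate_recording(beat_template(0.4),
                            recording_spec(n_beats = 22, period_jitter = 0.03,
                                           noise_sd = 0.1, drift_amplitude = 0.2,
                                           seed = 13))
  cfg <- run_config(n_beats = 9)
  ana <- analyze_ppg(rec$signal, cfg)
  avg <- ana$average
  # clean reference on the averaged grid, aligned at its own mid-rise point
  tpl <- rec$template
  ph <- seq(0, 0.999, by = 1e-3)
  ref0 <- sdppg:::rising_front_reference(template_eval(tpl, ph)) * 1e-3
  clean <- template_eval(tpl, avg$tau + ref0)
  resid_avg <- stats::sd(avg$ppg_avg - clean)
  resid_single <- vapply(ana$beats, function(b) {
    g <- (0:999) / 1000
    bs <- stats::spline(g, b$ppg, xout = avg$tau + b$ref_time, method = "fmm")$y
    stats::sd(bs - clean)
  }, numeric(1))
  expect_lt(resid_avg, min(resid_single))
})

test_that("resampled derivatives scale as duration^k against derivatives of the normalized pulse", {
  rec <- generate_recording(beat_template(0.3),
                            recording_spec(n_beats = 20, mean_period_s = 0.85,
                                           period_jitter = 0, noise_sd = 0,
                                           drift_amplitude = 0, seed = 6))
  ana <- analyze_ppg(rec$signal, run_config(n_beats = 9))
  b <- ana$beats[[4]]
  d <- b$original_duration
  # differentiate the normalized PPG with the same kernel, on the 1 s base
  nb <- sampled_signal(b$ppg, 1000)
  d2n <- snrd_differentiate(nb, 2)
  core <- 101:899
  expect_lt(max(abs(b$sd2[core] * d^2 - d2n$samples[core - 4])) /
            diff(range(d2n$samples)), 0.01)
  # and the normalized ratios are invariant to that scale factor
  expect_equal(ana$avg_features$agi,
               with(ana$avg_features, (b - c - d - e) / a))
})

test_that("positive amplitude scaling of the raw PPG leaves ratios and AGI unchanged", {
  rec <- clean_recording()
  cfg <- run_config(n_beats = 9)
  a1 <- analyze_ppg(rec$signal, cfg)
  scaled <- sampled_signal(rec$signal$samples * 37.5, rec$signal$fs)
  a2 <- analyze_ppg(scaled, cfg)
  for (col in c("b_over_a", "c_over_a", "d_over_a", "e_over_a", "agi")) {
    expect_equal(a2$avg_features[[col]], a1$avg_features[[col]],
                 tolerance = 1e-10)
  }
  expect_equal(a2$avg_features$a, 37.5 * a1$avg_features$a, tolerance = 1e-9)
})
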