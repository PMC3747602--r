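test_that("zero crossings interpolate sign changes and report exact zeros once", {
  expect_equal(zero_crossings(c(1, -1)), 0.5)
  expect_equal(zero_crossings(c(2, 1, 0.5)), numeric(0))
  expect_equal(zero_crossings(c(1, 0, -1)), 1)      # exact zero, once
  expect_equal(zero_crossings(c(1, 0, 0, -1)), 1)   # run of zeros collapses
  t <- seq(0, 2 - 1e-3, by = 1e-3)                  # two periods of sin at 1 kHz
  z <- zero_crossings(sin(2 * pi * t))
  interior <- z[z > 0.5 & z < 1999 - 0.5]
  expect_length(interior, 3)
  expect_equal(interior, c(500, 1000, 1500), tolerance = 1)
})

test_that("the ageing index follows its defining arithmetic", {
  expect_equal(agi(1, -0.5, -0.2, -0.3, 0.1), -0.1)
  expect_equal(agi(2, -1.0, -0.4, -0.6, 0.2), -0.1)  # scale invariance
  expect_equal(agi(1, 0, 0, 0, 0), 0)
  expect_error(agi(0, 1, 1, 1, 1), "nonzero")
})

test_that("detected wave locations agree with the generator's ground truth", {
  ana <- clean_analysis()
  f <- ana$avg_features
  truth <- clean_recording()$annotations$features
  # compare on the common normalized base: times relative to the reference
  ph <- seq(0, 0.999, by = 1e-3)
  ref0 <- sdppg:::rising_front_reference(
    template_eval(clean_recording()$template, ph)) * 1e-3
  for (w in c("a", "b", "c", "d", "e")) {
    expect_lt(abs(f[[paste0("t_", w)]] - (truth[[paste0("t_", w)]] - ref0)),
              0.002)
  }
  for (w in c("b_over_a", "c_over_a", "d_over_a", "e_over_a"))
    expect_lt(abs(f[[w]] - truth[[w]]), 0.01 * abs(truth[["b_over_a"]]))
  expect_true(with(f, t_a < t_b && t_b < t_c && t_c < t_d && t_d < t_e))
  expect_gt(f$a, 0)
  expect_lt(f$b, 0)
})

test_that("a monotone limb with inflections places c and d at fourth-derivative extrema", {
  # SDPPG with a true a/b pair, a monotone b-to-e limb (no c/d extrema),
  # and a true e maximum; the companion fourth derivative crosses zero
  # every 0.1 s so the c and d intervals exist but hold no extremum of the
  # expected polarity
  G <- function(t, mu, s) exp(-((t - mu) / s)^2)
  tau <- seq(-0.2, 0.7, by = 1e-3)
  sdppg <- 1.5 * G(tau, 0.03, 0.04) - 1.8 * G(tau, 0.13, 0.04) +
           1.2 / (1 + exp(-(tau - 0.30) / 0.05)) +
           1.0 * G(tau, 0.43, 0.05) - 0.8 * G(tau, 0.60, 0.05)
  d4 <- sin(2 * pi * 5 * (tau + 0.02))
  f <- detect_waves_core(tau, sdppg, d4)
  o <- oracle_detect_waves(tau, sdppg, d4)
  expect_false(is.null(o))
  expect_equal(unlist(f[c("t_a", "t_b", "t_c", "t_d", "t_e")]),
               o$t, tolerance = 1e-9, ignore_attr = TRUE)
  expect_true(f$fallback_c || f$fallback_d)
  expect_true(with(f, t_a < t_b && t_b < t_c && t_c < t_d && t_d < t_e))
})

test_that("scaling the SDPPG scales amplitudes but not ratios", {
  ws <- random_waveform_set(101)
  f1 <- detect_waves_core(ws$tau, ws$sdppg, ws$d4)
  f2 <- detect_waves_core(ws$tau, ws$sdppg * 10, ws$d4 * 10)
  expect_equal(f2$a, 10 * f1$a)
  expect_equal(f2$agi, f1$agi)
  expect_equal(f2$b_over_a, f1$b_over_a)
  expect_equal(f2$t_b, f1$t_b)
})

test_that("per-beat features on identical clean beats equal the averaged-waveform features", {
  ana <- clean_analysis()
  pb <- ana$beat_features
  expect_true(all(pb$ok))
  expect_lt(max(pb$agi) - min(pb$agi), 1e-6)
  expect_lt(abs(mean(pb$agi) - ana$avg_features$agi), 1e-3)
})

test_that("a corrupted beat yields a flagged row, not an abort", {
  ana <- clean_analysis()
  beats <- ana$beats
  bad <- beats[[3]]
  bad$ref_time <- NA_real_                   # simulate a lost rising front
  beats[[3]] <- bad
  pb <- per_beat_features(beats)
  expect_equal(nrow(pb), length(beats))
  expect_false(pb$ok[3])
  expect_match(pb$reason[3], "rising front")
  expect_true(all(pb$ok[-3]))
})

test_that("the per-beat baseline agrees with the full pipeline on clean data", {
  rec <- clean_recording()
  cfg <- run_config(n_beats = 15)
  full <- analyze_ppg(rec$signal, cfg)
  bl <- baseline_per_beat(rec$signal, 15, cfg)
  expect_true(all(bl$ok))
  expect_lt(abs(mean(bl$agi) - full$avg_features$agi),
            0.01 * abs(full$avg_features$agi))
  # noise-free: both modes are essentially dispersion-free
  expect_lt(stats::sd(bl$agi), 1e-3)
  expect_lt(full$sds[["agi"]], 1e-3)
})
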