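test_that("the clean-template ageing index is strictly monotone in stiffness", {
  v <- vapply(seq(0, 1, by = 0.1), template_agi, numeric(1))
  expect_true(all(diff(v) > 0))
  expect_lt(v[1], -1.7)          # range covers the physiological span
  expect_gt(v[11], 0.4)
})

test_that("deepening the b trough (higher stiffness) raises the ageing index", {
  f_lo <- beat_template(0.2)$features
  f_hi <- beat_template(0.8)$features
  expect_gt(f_hi$agi, f_lo$agi)
})

test_that("stiffness inversion attains requested targets within 0.01", {
  for (target in c(-1.5, -1.0, -0.45, 0.2)) {
    s <- stiffness_for_agi(target)
    expect_lt(abs(template_agi(s) - target), 0.01)
  }
  expect_error(stiffness_for_agi(5), "attainable range")
  expect_error(stiffness_for_agi(-5), "attainable range")
})

test_that("recordings are bit-reproducible under a fixed seed", {
  tpl <- beat_template(0.5)
  r1 <- generate_recording(tpl, recording_spec(n_beats = 6, seed = 77))
  r2 <- generate_recording(tpl, recording_spec(n_beats = 6, seed = 77))
  expect_identical(r1$signal$samples, r2$signal$samples)
  r3 <- generate_recording(tpl, recording_spec(n_beats = 6, seed = 78))
  expect_false(identical(r1$signal$samples, r3$signal$samples))
})

test_that("generation does not disturb the caller's random stream", {
  set.seed(123); before <- rnorm(3)
  set.seed(123)
  invisible(generate_recording(beat_template(0.5),
                               recording_spec(n_beats = 4, seed = 9)))
  expect_identical(rnorm(3), before)
})

test_that("the clean pipeline reproduces the annotated ageing index", {
  rec <- clean_recording()
  ana <- clean_analysis()
  expect_lt(abs(ana$avg_features$agi - rec$annotations$agi), 5e-3)
})

test_that("jitter-free recordings concentrate AC power on integer harmonics after normalization", {
  ana <- clean_analysis()
  b <- ana$beats[[2]]
  x <- b$ppg - mean(b$ppg)
  g <- (0:999) / 1000
  amp2 <- function(f) (2 * Mod(mean(x * exp(-2i * pi * f * g))))^2
  on_integer <- sum(vapply(1:8, amp2, numeric(1)))
  total <- 2 * sum(Mod(stats::fft(x)[2:500] / 1000)^2) * 2
  expect_gt(on_integer / total, 0.95)
})

test_that("more noise never reduces the beat-to-beat AGI dispersion (Monte Carlo)", {
  sds <- vapply(1:8, function(s) {
    tpl <- beat_template(0.5)
    res <- vapply(c(0.02, 0.08), function(ns) {
      rec <- generate_recording(tpl, recording_spec(n_beats = 22,
                                                    noise_sd = ns,
                                                    seed = 400 + s))
      analyze_ppg(rec$signal, run_config(n_beats = 10))$sds[["agi"]]
    }, numeric(1))
    res[2] - res[1]
  }, numeric(1))
  expect_gte(mean(sds >= 0), 0.75)
  expect_gt(mean(sds), 0)
})

test_that("cohort ground truth follows the generating model exactly when noise-free", {
  coh <- generate_cohort(n_healthy = 6, n_patient = 5, residual_sd = 0,
                         seed = 11, build_templates = FALSE)
  rec <- coh$records
  h <- rec[rec$group == "healthy", ]
  p <- rec[rec$group == "patient", ]
  expect_equal(h$agi, 0.019 * h$age - 1.556, tolerance = 1e-12)
  expect_equal(p$agi, 0.019 * p$age - 1.556 + 0.359, tolerance = 1e-12)
  coh2 <- generate_cohort(n_healthy = 4, n_patient = 0, seed = 5,
                          build_templates = FALSE)
  expect_true(all(coh2$records$group == "healthy"))
  expect_error(generate_cohort(n_healthy = 3, n_patient = 0, intercept = 10,
                               residual_sd = 0, seed = 1,
                               build_templates = FALSE),
               "attainable range")
})

test_that("subject templates attain their ground-truth targets", {
  coh <- generate_cohort(n_healthy = 4, n_patient = 3, seed = 21)
  got <- vapply(coh$templates, function(tp) tp$features$agi, numeric(1))
  expect_lt(max(abs(got - coh$records$agi)), 0.01)
})

test_that("recordings round-trip through the plain-text writer", {
  rec <- generate_recording(beat_template(0.5),
                            recording_spec(n_beats = 4, seed = 31))
  pref <- file.path(withr::local_tempdir(), "rec")
  paths <- write_recording(rec, pref)
  back <- read_ppg_signal(paths[["signal"]])
  expect_equal(back$fs, 1000)
  expect_equal(back$samples, rec$signal$samples, tolerance = 1e-9)
  ann <- utils::read.csv(paths[["annotations"]])
  expect_equal(nrow(ann), 4)
  expect_true(all(c("onset_s", "period_s", "t_a_global") %in% names(ann)))
})
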