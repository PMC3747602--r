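make_cohort <- function(age, agi, group = "healthy") {
  data.frame(subject_id = sprintf("s%d", seq_along(age)), age = age,
             group = group, agi = agi, stringsAsFactors = FALSE)
}

test_that("points on a line are recovered exactly with r = 1", {
  age <- c(21, 30, 38, 47, 55, 66)
  df <- make_cohort(age, 0.019 * age - 1.556)
  m <- fit_agi_age(df)
  expect_equal(m$slope, 0.019, tolerance = 1e-12)
  expect_equal(m$intercept, -1.556, tolerance = 1e-12)
  expect_equal(m$r, 1)
  expect_equal(m$residual_sd, 0, tolerance = 1e-12)
  expect_error(fit_agi_age(df[1:2, ]), "at least 3")
  expect_error(fit_agi_age(make_cohort(c(40, 40, 40), c(1, 2, 3))),
               "variance")
})

test_that("noisy simulated cohorts recover the generating slope on average", {
  slopes <- vapply(1:200, function(s) {
    set.seed(s)
    age <- runif(21, 21, 66)
    df <- make_cohort(age, 0.019 * age - 1.556 + rnorm(21, 0, 0.126))
    fit_agi_age(df)$slope
  }, numeric(1))
  expect_lt(abs(mean(slopes) - 0.019) / 0.019, 0.15)
})

test_that("differences from the model evaluate the printed line", {
  model <- list(slope = 0.019, intercept = -1.556)
  df <- make_cohort(c(50, 50), c(0.019 * 50 - 1.556, -0.5),
                    group = c("healthy", "patient"))
  ba <- bland_altman_vs_model(df, model)
  expect_equal(ba$records$diff[1], 0)
  expect_equal(ba$records$diff[2], 0.106)
  # OLS residuals of the fitting group average zero
  set.seed(1)
  age <- runif(12, 21, 66)
  df2 <- make_cohort(age, 0.019 * age - 1.556 + rnorm(12, 0, 0.1))
  m <- fit_agi_age(df2)
  ba2 <- bland_altman_vs_model(df2, m)
  expect_equal(ba2$summary$mean[ba2$summary$group == "healthy"], 0,
               tolerance = 1e-12)
})

test_that("the Welch comparison matches its closed form and limits", {
  # identical groups: t = 0, p = 1
  x <- c(0.1, -0.2, 0.05, 0.3)
  r0 <- compare_groups(x, x)
  expect_equal(r0$t, 0)
  expect_equal(r0$p_value, 1)
  # large separation drives p below 1e-6
  r1 <- compare_groups(rnorm(10, 0, 1e-3), rnorm(10, 5, 1e-3))
  expect_lt(r1$p_value, 1e-6)
  # hand evaluation of the Welch statistic on vectors with exact moments
  mk <- function(m, s) { v <- 1:10; m + s * (v - mean(v)) / stats::sd(v) }
  g1 <- mk(5, 1); g2 <- mk(6, 2)
  r <- compare_groups(g1, g2)
  se <- sqrt(1 / 10 + 4 / 10)
  t_hand <- (5 - 6) / se
  df_hand <- se^4 / ((1 / 10)^2 / 9 + (4 / 10)^2 / 9)
  expect_equal(r$t, t_hand)
  expect_equal(r$df, df_hand)
  expect_error(compare_groups(rep(1, 5), rep(2, 5)), "zero variance")
})

test_that("the Welch p-value falls monotonically with the group shift", {
  set.seed(2)
  base <- rnorm(21, 0, 0.126)
  pat0 <- rnorm(20, 0, 0.126)
  ps <- vapply(c(0.05, 0.15, 0.25, 0.359), function(d)
    compare_groups(base, pat0 + d)$p_value, numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("cohort analysis flags missing patient groups instead of testing", {
  set.seed(3)
  age <- runif(10, 21, 66)
  df <- make_cohort(age, 0.019 * age - 1.556 + rnorm(10, 0, 0.05))
  res <- cohort_analysis(df)
  expect_null(res$test)
  expect_match(res$test_note, "not applicable")
})
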