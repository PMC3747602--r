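#' Linear ageing-index-versus-age model
#'
#' Ordinary least squares of AGI on age over one cohort group (the Gaussian
#' identity-link generalized linear model). Reports the Pearson correlation
#' of the raw (age, AGI) pairs and the standard deviation of the residuals.
#'
#' @param records Cohort data frame (see [read_cohort()]) with an `agi`
#'   column.
#' @param group Which group to fit on (default `"healthy"`).
#' @return List of class `agi_age_model`: `slope` (AGI per year),
#'   `intercept`, `r`, `residual_sd`, `n`, and the underlying `lm` fit.
#' @export
fit_agi_age <- function(records, group = "healthy") {
  records <- validate_cohort(as.data.frame(records))
  if (!"agi" %in% names(records)) stop("records lack an `agi` column")
  sub <- records[records$group == group & is.finite(records$agi), , drop = FALSE]
  if (nrow(sub) < 3L)
    stop(sprintf("need at least 3 records in group '%s', have %d", group, nrow(sub)))
  if (stats::sd(sub$age) == 0) stop("zero age variance in the fitting group")
  fit <- stats::lm(agi ~ age, data = sub)
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r = stats::cor(sub$age, sub$agi),
                 residual_sd = stats::sd(stats::residuals(fit)),
                 n = nrow(sub), fit = fit),
            class = "agi_age_model")
}

#' Evaluate an ageing-index model at given ages
#' @param model An `agi_age_model`, or a list/vector with `slope` and
#'   `intercept`.
#' @param age Ages in years.
#' @return Predicted AGI values.
#' @export
predict_agi <- function(model, age) {
  model$intercept + model$slope * age
}

#' Bland-Altman-style differences from the age model
#'
#' Per-record difference `agi - model(age)` with per-group mean and
#' standard deviation; the healthy-group SD is the model's agreement
#' spread.
#'
#' @param records Cohort data frame with `agi`.
#' @param model An `agi_age_model` (or list with `slope`, `intercept`).
#' @return List of class `bland_altman`: `records` (input plus `model_agi`,
#'   `diff`) and `summary` (per-group data frame with `n`, `mean`, `sd`).
#' @export
bland_altman_vs_model <- function(records, model) {
  records <- validate_cohort(as.data.frame(records))
  if (!"agi" %in% names(records)) stop("records lack an `agi` column")
  records$model_agi <- predict_agi(model, records$age)
  records$diff <- records$agi - records$model_agi
  summ <- do.call(rbind, lapply(levels(records$group), function(g) {
    d <- records$diff[records$group == g]
    d <- d[is.finite(d)]
    data.frame(group = g, n = length(d),
               mean = if (length(d)) mean(d) else NA_real_,
               sd = if (length(d) >= 2L) stats::sd(d) else NA_real_)
  }))
  structure(list(records = records, summary = summ), class = "bland_altman")
}

#' Welch two-sample comparison of model differences
#'
#' Unequal-variance (Welch) two-sample t-test between the healthy and
#' patient differences from the age model, two-sided.
#'
#' @param diffs_healthy,diffs_patient Numeric vectors of per-subject model
#'   differences.
#' @return List with `t`, `df`, `p_value`, group means, and the underlying
#'   `htest`.
#' @export
compare_groups <- function(diffs_healthy, diffs_patient) {
  x <- diffs_healthy[is.finite(diffs_healthy)]
  y <- diffs_patient[is.finite(diffs_patient)]
  if (length(x) < 2L || length(y) < 2L)
    stop("need at least 2 finite values per group")
  if (stats::sd(x) == 0 && stats::sd(y) == 0)
    stop("zero variance in both groups; the test statistic is undefined")
  ht <- stats::t.test(x, y, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, mean_healthy = mean(x), mean_patient = mean(y),
       htest = ht)
}

#' Full cohort analysis
#'
#' Fits the healthy-group AGI-age model, computes Bland-Altman differences
#' for everyone, and compares healthy against patient differences with the
#' Welch test (skipped when either group is absent or too small).
#'
#' @param records Cohort data frame with `agi`.
#' @return List of class `cohort_analysis`: `model`, `bland_altman`,
#'   `test` (or `NULL` with `test_note`).
#' @export
cohort_analysis <- function(records) {
  model <- fit_agi_age(records, group = "healthy")
  ba <- bland_altman_vs_model(records, model)
  dh <- ba$records$diff[ba$records$group == "healthy"]
  dp <- ba$records$diff[ba$records$group == "patient"]
  test <- NULL; note <- ""
  if (sum(is.finite(dp)) >= 2L && sum(is.finite(dh)) >= 2L) {
    test <- compare_groups(dh, dp)
  } else {
    note <- "group comparison not applicable: fewer than 2 patient records"
  }
  structure(list(model = model, bland_altman = ba, test = test,
                 test_note = note),
            class = "cohort_analysis")
}
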