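test_that("CWRES matches the hand linearisation on a one-observation subject", {
  m <- plain_model(0.756, 4.89, omega = c(CL = 0.3),
                   error = residual_error("proportional", 0.2))
  dat <- toy_dataset(list(list(dose_times = 0, amounts = 60, durations = 1,
                               obs_times = 2, dv = 13.2, cov = list())))
  fit <- pkfit_at(dat, m)
  g <- gof_residuals(fit)
  # independent hand computation of the 1-D FOCE linearisation
  ev <- dosing_events(0, 60, 1)
  eta_hat <- map_eta(dat, m)$eta_CL
  f_eta <- function(e) concentration_at(2, ev, 0.756 * exp(e), 4.89)
  gg <- (f_eta(eta_hat + 1e-5) - f_eta(eta_hat - 1e-5)) / 2e-5
  f0 <- f_eta(eta_hat)
  covm <- gg^2 * 0.3^2 + 0.2^2 * f0^2
  want <- (13.2 - (f0 - gg * eta_hat)) / sqrt(covm)
  expect_equal(g$CWRES, want, tolerance = 1e-4)
  expect_equal(g$PRED, f_eta(0), tolerance = 1e-10)
  expect_equal(g$IPRED, f0, tolerance = 1e-10)
})

test_that("CWRES is calibrated on data simulated from the fitted model", {
  m2 <- vanco_model("model2")
  dat <- quiet_cohort(cohort_config(125, "augmented", seed = 33), m2)
  fit <- quiet_fit(dat, m2)
  g <- gof_residuals(fit)
  expect_equal(nrow(g), 250)
  expect_lt(abs(mean(g$CWRES)), 0.1)
  expect_gt(sd(g$CWRES), 0.85)
  expect_lt(sd(g$CWRES), 1.15)
})

test_that("CWRES vanishes on noise-free data", {
  gen <- vanco_model("model2")
  gen$omega <- c(CL = 0)
  gen$error <- residual_error("proportional", 0)
  dat <- simulate_cohort(cohort_config(5, "augmented", seed = 6), gen)
  eval_model <- vanco_model("model2")
  eval_model$omega <- c(CL = 1e-3)
  eval_model$error <- residual_error("proportional", 1e-3)
  fit <- pkfit_at(dat, eval_model)
  g <- gof_residuals(fit)
  expect_lt(max(abs(g$CWRES)), 0.05)
})

test_that("prediction-error metrics match the printed formulas", {
  m <- prediction_metrics(c(10, 20), c(8, 25))
  expect_equal(m$MPE, -1.5)
  expect_equal(m$MAE, 3.5)
  expect_equal(m$MPE_pct, 2.5)
  expect_equal(m$MAE_pct, 22.5)
  expect_equal(m$RMSE, sqrt(14.5))
  # all-zero when predictions equal observations
  z <- prediction_metrics(c(3, 7, 9), c(3, 7, 9))
  expect_true(all(unlist(z[c("MPE", "MAE", "MPE_pct", "MAE_pct", "RMSE")]) == 0))
  # zero observations excluded from relative metrics
  e <- prediction_metrics(c(1, 2), c(0, 4))
  expect_equal(e$n_excluded_relative, 1)
  expect_equal(e$MPE_pct, -50)
  # inequalities and order invariance on random inputs
  set.seed(12)
  for (r in 1:10) {
    ip <- runif(20, 1, 30); ob <- runif(20, 1, 30)
    mm <- prediction_metrics(ip, ob)
    expect_gte(mm$RMSE, mm$MAE)
    expect_gte(mm$MAE, abs(mm$MPE))
    expect_gte(mm$MAE_pct, abs(mm$MPE_pct))
    o <- sample(20)
    expect_equal(prediction_metrics(ip[o], ob[o]), mm)
  }
})

test_that("Bayesian forecasting drives external validation towards zero error", {
  m2 <- vanco_model("model2")
  mlow <- vanco_model("model2")
  mlow$error <- residual_error("proportional", 1e-3)
  ext <- simulate_cohort(cohort_config(15, "augmented", seed = 91), mlow)
  val <- external_validation(mlow, ext)
  expect_lt(val$MAE_pct, 1)
  expect_equal(val$n, 30)
  # with realistic noise, errors are moderate and invariants hold
  ext2 <- quiet_cohort(cohort_config(15, "augmented", seed = 92), m2)
  val2 <- external_validation(m2, ext2)
  expect_gte(val2$RMSE, val2$MAE)
  expect_gte(val2$MAE, abs(val2$MPE))
})

test_that("paired Wilcoxon comparison matches a sign-enumeration oracle", {
  id <- list(statistic = NA, p_value = 1)
  same <- structure(list(abs_errors = c(1, 2, 3), n = 3), class = "pk_validation")
  out <- compare_models_paired(same, same)
  expect_true(out$degenerate)
  expect_equal(out$p_value, 1)
  expect_false(out$different)
  set.seed(5)
  for (r in 1:5) {
    n <- 9
    a <- runif(n, 1, 10)
    d <- runif(n, -2, 2)
    va <- structure(list(abs_errors = a, n = n), class = "pk_validation")
    vb <- structure(list(abs_errors = a - d, n = n), class = "pk_validation")
    got <- compare_models_paired(va, vb)
    want <- signed_rank_p_enum(d)
    wt <- wilcox.test(a, a - d, paired = TRUE, exact = TRUE)
    expect_equal(wt$p.value, want, tolerance = 1e-10)
    expect_equal(got$p_value, wt$p.value, tolerance = 1e-10)
  }
})

test_that("VPC percentiles are ordered, calibrated, and detect misfit", {
  m2 <- vanco_model("model2")
  dat <- quiet_cohort(cohort_config(100, "augmented", seed = 55), m2)
  fit <- pkfit_at(dat, m2)
  v <- vpc(fit, n_sim = 200, seed = 9)
  tab <- v$table
  for (b in unique(tab$bin)) {
    tb <- tab[tab$bin == b, ]
    tb <- tb[order(tb$percentile), ]
    expect_true(all(diff(tb$simulated) > 0))
    expect_true(all(diff(tb$observed) >= 0))
    expect_true(all(tb$ci_lower <= tb$simulated & tb$simulated <= tb$ci_upper))
  }
  # correct model: ~90% of observations inside the 90% PI (binomial tolerance)
  n <- 200
  expect_gt(v$coverage, 0.90 - 3 * sqrt(0.9 * 0.1 / n))
  expect_lt(v$coverage, 0.90 + 3.5 * sqrt(0.9 * 0.1 / n))
  # deterministic given the seed
  v2 <- vpc(fit, n_sim = 200, seed = 9)
  expect_identical(v$table, v2$table)
  # a grossly inflated volume departs from nominal coverage
  mbad <- vanco_model("model2")
  mbad$theta["TVV"] <- 3 * mbad$theta["TVV"]
  fitbad <- pkfit_at(dat, mbad)
  vbad <- vpc(fitbad, n_sim = 200, seed = 9)
  expect_lt(vbad$coverage, 0.80)
})

test_that("bootstrap of a single subject is degenerate and unbiased", {
  m2 <- vanco_model("model2")
  dat <- quiet_cohort(cohort_config(1, "augmented", seed = 44), m2)
  fit <- quiet_fit(dat, m2)
  # all resamples are the same subject; skip refitting variance entirely
  b <- suppressWarnings(bootstrap_pk(fit, n_reps = 5, seed = 2))
  expect_true(all(abs(b$table$upper - b$table$lower) < 1e-6))
  expect_true(all(abs(b$table$bias_pct) < 0.5))
})
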