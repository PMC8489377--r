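# One subject, one 60 mg / 1 h infusion, CL/V fixed; prediction at t known in
# closed form, so conditional densities can be hand-checked.
one_obs_subject <- function(dv, t = 2, cl = 0.756, v = 4.89) {
  toy_dataset(list(list(dose_times = 0, amounts = 60, durations = 1,
                        obs_times = t, dv = dv, cov = list())))
}

test_that("conditional -2LL matches hand-written Gaussian densities", {
  cl <- 0.756; v <- 4.89
  f <- concentration_at(2, dosing_events(0, 60, 1), cl, v)
  m_add <- plain_model(cl, v, error = residual_error("additive", 1))
  # observation equal to the prediction, additive sigma = 1: -2 log phi(0)
  expect_equal(unname(individual_minus2ll(one_obs_subject(f), m_add, 0)),
               log(2 * pi), tolerance = 1e-12)
  # two observations, proportional error: compare against dnorm
  m_prop <- plain_model(cl, v, error = residual_error("proportional", 0.25))
  dat2 <- toy_dataset(list(list(dose_times = 0, amounts = 60, durations = 1,
                                obs_times = c(1.5, 6), dv = c(9, 4.4),
                                cov = list())))
  ff <- concentration_at(c(1.5, 6), dosing_events(0, 60, 1), cl, v)
  want <- -2 * sum(dnorm(c(9, 4.4), ff, 0.25 * ff, log = TRUE))
  expect_equal(unname(individual_minus2ll(dat2, m_prop, 0)), want,
               tolerance = 1e-10)
  # strictly increasing in |y - f|
  vals <- sapply(c(0, 0.5, 1, 2), function(d)
    individual_minus2ll(one_obs_subject(f + d), m_add, 0))
  expect_true(all(diff(vals) > 0))
})

test_that("conditional modes match a dense grid search and known limits", {
  m <- plain_model(0.756, 4.89, omega = c(CL = 0.4),
                   error = residual_error("proportional", 0.2))
  dat <- one_obs_subject(14, t = 1.5)
  eb <- map_eta(dat, m)
  # brute-force grid oracle on the 1-D joint objective
  grid <- seq(-2, 2, by = 1e-3)
  qg <- sapply(grid, function(e)
    individual_minus2ll(dat, m, e) + e^2 / 0.4^2 + log(2 * pi * 0.4^2))
  expect_lt(abs(eb$eta_CL - grid[which.min(qg)]), 2e-3)
  # infinitely strong prior pulls the mode to zero
  m0 <- m; m0$omega <- c(CL = 1e-5)
  expect_lt(abs(map_eta(dat, m0)$eta_CL), 1e-6)
  # noise-free data generated at a known eta is recovered under a weak prior
  eta_true <- 0.37
  f <- concentration_at(c(1.5, 7), dosing_events(0, 60, 1),
                        0.756 * exp(eta_true), 4.89)
  datf <- toy_dataset(list(list(dose_times = 0, amounts = 60, durations = 1,
                                obs_times = c(1.5, 7), dv = f, cov = list())))
  mw <- plain_model(0.756, 4.89, omega = c(CL = 5),
                    error = residual_error("proportional", 0.01))
  expect_equal(map_eta(datf, mw)$eta_CL, eta_true, tolerance = 1e-3)
})

test_that("FOCE objective reduces to the fixed-effects -2LL when omega is zero", {
  m <- plain_model(0.756, 4.89, omega = c(CL = 0),
                   error = residual_error("proportional", 0.3))
  dat <- quiet_cohort(cohort_config(6, "augmented", seed = 21),
                      vanco_model("model2"))
  design_obs <- dat[dat$EVID == 0, ]
  # closed form: sum over observations of the Gaussian -2 log density
  typ <- typical_parameters(m, design_obs[1, , drop = FALSE])  # no covariates
  want <- 0
  for (i in unique(dat$ID)) {
    di <- dat[dat$ID == i, ]
    ev <- dosing_events(di$TIME[di$EVID == 1], di$AMT[di$EVID == 1],
                        di$DUR[di$EVID == 1])
    f <- concentration_at(di$TIME[di$EVID == 0], ev, typ$CL, typ$V)
    want <- want - 2 * sum(dnorm(di$DV[di$EVID == 0], f, 0.3 * f, log = TRUE))
  }
  expect_equal(ofv_foce(dat, m), want, tolerance = 1e-8)
})

test_that("FOCE objective tracks the Gauss-Hermite reference on small cohorts", {
  m2 <- vanco_model("model2")
  for (s in 1:4) {
    dat <- quiet_cohort(cohort_config(sample(2:5, 1), "augmented", seed = 300 + s), m2)
    foce <- ofv_foce(dat, m2)
    quad <- ofv_quadrature_oracle(dat, m2, 64)
    expect_lt(abs(foce - quad), 1)
  }
  # node-count self-convergence on a one-subject toy
  dat <- quiet_cohort(cohort_config(1, "augmented", seed = 77), m2)
  expect_lt(abs(ofv_quadrature_oracle(dat, m2, 32) -
                ofv_quadrature_oracle(dat, m2, 64)), 1e-6)
})

test_that("quadrature agrees with a Monte-Carlo marginal likelihood", {
  m <- vanco_model("model2")
  dat <- quiet_cohort(cohort_config(1, "augmented", seed = 13), m)
  quad <- ofv_quadrature_oracle(dat, m, 64)
  set.seed(101)
  draws <- rnorm(2e5, 0, m$omega[["CL"]])
  # direct Monte-Carlo evaluation of E_eta[p(y | eta)] from the raw records
  ev <- dosing_events(dat$TIME[dat$EVID == 1], dat$AMT[dat$EVID == 1],
                      dat$DUR[dat$EVID == 1])
  tt <- dat$TIME[dat$EVID == 0]
  y <- dat$DV[dat$EVID == 0]
  typ <- typical_parameters(m, dat[1, c("WT", "HT", "SCR"), drop = FALSE])
  lik <- vapply(draws, function(e) {
    f <- concentration_at(tt, ev, typ$CL * exp(e), typ$V)
    prod(dnorm(y, f, m$error$sigma * f))
  }, numeric(1))
  l_hat <- mean(lik)
  se <- sd(lik) / sqrt(length(lik))
  # exp(-quad/2) and the MC average both estimate E_eta[p(y|eta)]
  expect_lt(abs(exp(-quad / 2) - l_hat), 3 * se)
})

test_that("population fit is exchangeable and recovers noise-free truth", {
  m2 <- vanco_model("model2")
  dat <- quiet_cohort(cohort_config(12, "augmented", seed = 51), m2)
  f1 <- ofv_foce(dat, m2)
  # permute subject blocks
  ids <- unique(dat$ID)
  perm <- c(ids[4:12], ids[1:3])
  dat2 <- do.call(rbind, lapply(perm, function(i) dat[dat$ID == i, ]))
  expect_equal(ofv_foce(dat2, m2), f1, tolerance = 1e-8)
  # near-noise-free, omega = 0 data: recovery of CL and V to tolerance
  m0 <- vanco_model("model2")
  m0$omega <- c(CL = 0)
  m0$error <- residual_error("proportional", 1e-3)
  datnf <- simulate_cohort(cohort_config(8, "augmented", seed = 4), m0)
  mstart <- vanco_model("model2")
  mstart$theta["TVCL"] <- 0.6; mstart$theta["TVV"] <- 4
  fit <- quiet_fit(datnf, mstart,
                   init = c(omega_CL = 0.02, sigma = 0.01))
  expect_equal(unname(fit$theta[["TVCL"]]), 0.756, tolerance = 0.005)
  expect_equal(unname(fit$theta[["TVV"]]), 4.89, tolerance = 0.005)
})

test_that("a nested model with a spurious covariate never fits worse", {
  m2 <- vanco_model("model2")
  dat <- quiet_cohort(cohort_config(24, "augmented", seed = 61), m2)
  fit_base <- quiet_fit(dat, m2)
  bigger <- pk_model("m2+scr",
    cl_terms = list(pk_term("power", "WT", 4.6, "WT"),
                    pk_term("expslope", "SCR", 16.8, "SCR")),
    v_terms = list(pk_term("power", "WT", 4.6, "WT")),
    theta = c(TVCL = 0.756, TVV = 4.89, CL_WT = 1.03, V_WT = 0.918,
              CL_SCR = 0),
    omega = c(CL = 0.312), error = residual_error("proportional", 0.319))
  fit_big <- quiet_fit(dat, bigger)
  expect_lte(fit_big$ofv, fit_base$ofv + 1e-3)
})

test_that("shrinkage behaves in the rich-data and no-information limits", {
  m2 <- vanco_model("model2")
  # rich design: 8 observations per subject
  cfg <- cohort_config(24, "augmented", seed = 71)
  set.seed(71)
  cov <- sample_covariates(cfg)
  subjects <- lapply(seq_len(24), function(i) {
    reg <- build_dosing_regimen(cov$WT[i], 3, cfg)
    typ <- typical_parameters(m2, cov[i, , drop = FALSE])
    eta <- rnorm(1, 0, 0.312)
    tt <- c(1.5, 4, 7.5, 12, 20, 31.5, 33.5, 40)
    f <- concentration_at(tt, reg, typ$CL * exp(eta), typ$V)
    dv <- f * (1 + rnorm(8, 0, 0.15))
    list(dose_times = reg$start_time, amounts = reg$amount,
         durations = reg$duration, obs_times = tt, dv = dv,
         cov = list(WT = cov$WT[i]))
  })
  rich <- toy_dataset(subjects)
  fit <- quiet_fit(rich, m2)
  expect_lt(fit$shrinkage[["eta_CL"]], 10)
  # no information: enormous (additive) residual error pulls all modes to zero
  mblur <- vanco_model("model2")
  mblur$error <- residual_error("additive", 1e3)
  dat <- quiet_cohort(cohort_config(10, "augmented", seed = 81), m2)
  eb <- map_eta(dat, mblur)
  shr <- 100 * (1 - sd(eb$eta_CL) / 0.312)
  expect_gt(shr, 95)
})

test_that("estimator bias shrinks as the cohort grows", {
  m2 <- vanco_model("model2")
  bias_at <- function(n, seeds) {
    est <- sapply(seeds, function(s) {
      dat <- quiet_cohort(cohort_config(n, "augmented", seed = s), m2)
      quiet_fit(dat, m2)$theta[["TVCL"]]
    })
    abs(median(est) - 0.756)
  }
  b <- c(bias_at(16, 900 + 1:6), bias_at(64, 920 + 1:6), bias_at(256, 940 + 1:3))
  expect_lt(b[3], b[1])
  expect_lt(b[2], b[1] + 0.02)   # monotone within noise at simulation scale
})
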