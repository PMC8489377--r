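test_that("Schwartz eGFR uses the published age-class coefficients", {
  # with HT = SCR = 1 the formula returns 88.4 * k
  expect_equal(egfr_schwartz(1, 1, "preterm<1y") / 88.4, 0.33)
  expect_equal(egfr_schwartz(1, 1, "term<1y") / 88.4, 0.45)
  expect_equal(egfr_schwartz(1, 1, "2-12y") / 88.4, 0.55)
  expect_equal(egfr_schwartz(50, 18.95, "term<1y"), 104.96, tolerance = 1e-4)
  # scaling symmetries
  expect_equal(egfr_schwartz(50, 2 * 18.95, "term<1y"),
               egfr_schwartz(50, 18.95, "term<1y") / 2)
  expect_equal(egfr_schwartz(3 * 50, 3 * 18.95, "term<1y"),
               egfr_schwartz(50, 18.95, "term<1y"))
  expect_error(egfr_schwartz(50, 0, "term<1y"), "SCR")
})

test_that("renal-function classification partitions eGFR with the 30/86 cuts", {
  expect_equal(as.character(classify_renal_function(c(29.9, 30, 85.56, 86, 280))),
               c("excluded", "normal", "normal", "augmented", "augmented"))
  # no gaps or overlaps over a fine grid
  g <- seq(0, 400, by = 0.25)
  cls <- classify_renal_function(g)
  expect_false(anyNA(cls))
  expect_true(all(g[cls == "excluded"] < 30))
  expect_true(all(g[cls == "normal"] >= 30 & g[cls == "normal"] < 86))
  expect_true(all(g[cls == "augmented"] >= 86))
})

test_that("registry models reproduce the published typical values", {
  m1 <- vanco_model("model1"); m2 <- vanco_model("model2"); m3 <- vanco_model("model3")
  tp2 <- typical_parameters(m2, data.frame(WT = 4.6))
  expect_equal(tp2$CL, 0.756)
  expect_equal(tp2$V, 4.89)
  # at the centering medians the SCR factor e^theta5 remains (estimable form)
  tp1 <- typical_parameters(m1, data.frame(WT = 2.25, SCR = 27.1))
  expect_equal(tp1$CL, 0.407 * exp(-0.533), tolerance = 1e-12)
  expect_equal(tp1$CL, 0.2388, tolerance = 1e-3)
  expect_equal(tp1$V, 1.86)
  tp3 <- typical_parameters(m3, data.frame(WT = 3.45, SCR = 19))
  expect_equal(tp3$CL, 0.707 * exp(-0.377), tolerance = 1e-12)
  expect_equal(tp3$CL, 0.4850, tolerance = 1e-3)
  expect_equal(tp3$V, 3.39)
  expect_error(typical_parameters(m1, data.frame(WT = 2.25)), "SCR")
})

test_that("clearance is monotone in the covariates as the signs dictate", {
  wt <- seq(1.2, 13, length.out = 30)
  scr <- seq(14, 200, length.out = 30)
  m1 <- vanco_model("model1"); m2 <- vanco_model("model2"); m3 <- vanco_model("model3")
  cl_wt1 <- typical_parameters(m1, data.frame(WT = wt, SCR = 27.1))$CL
  cl_scr1 <- typical_parameters(m1, data.frame(WT = 2.25, SCR = scr))$CL
  cl_wt2 <- typical_parameters(m2, data.frame(WT = wt))$CL
  cl_scr3 <- typical_parameters(m3, data.frame(WT = 3.45, SCR = scr))$CL
  expect_true(all(diff(cl_wt1) > 0))
  expect_true(all(diff(cl_scr1) < 0))
  expect_true(all(diff(cl_wt2) > 0))
  expect_true(all(diff(cl_scr3) < 0))
})

test_that("maturation forms honour their sigmoid midpoints and identities", {
  # form III: MF = 0.5 exactly at AGE = TM50 (base CL 1, WT at median)
  mat3 <- list(TM50 = 3, HILL = 2.2)
  expect_equal(maturation_cl("III", 1, data.frame(WT = 4, AGE = 3), 4,
                             mat = mat3), 0.5)
  # form IV: exponent theta0 - kmax/2 at WT = k50
  mat4 <- list(THETA0 = 1.2, KMAX = 0.5, K50 = 4, HILL = 3)
  wt <- 4
  got <- maturation_cl("IV", 1, data.frame(WT = wt), 2, mat = mat4)
  expect_equal(got, (wt / 2)^(1.2 - 0.25))
  # form V with age at k50
  mat5 <- list(THETA0 = 1.1, KMAX = 0.4, K50 = 6, HILL = 2)
  expect_equal(maturation_cl("V", 1, data.frame(WT = 4, AGE = 6), 2, mat = mat5),
               (4 / 2)^(1.1 - 0.2))
  # form I with unit exponents at the median reduces CL and V to typicals
  m <- maturation_model("I", wt_median = 3.3,
                        theta = c(TVCL = 0.6, TVV = 2.5, CL_WT = 1, V_WT = 1))
  tp <- typical_parameters(m, data.frame(WT = 3.3))
  expect_equal(tp$CL, 0.6)
  expect_equal(tp$V, 2.5)
  # form II uses the fixed 0.75 exponent
  m2 <- maturation_model("II", wt_median = 3.3,
                         theta = c(TVCL = 0.6, TVV = 2.5))
  tp2 <- typical_parameters(m2, data.frame(WT = 6.6))
  expect_equal(tp2$CL, 0.6 * 2^0.75)
  expect_equal(tp2$V, 2.5 * 2)
  expect_error(maturation_model("VI", 3.3))
})

test_that("between-subject variability is a log-normal multiplier", {
  typ <- data.frame(CL = 0.756, V = 4.89)
  expect_equal(apply_bsv(typ, 0, 0), list(CL = 0.756, V = 4.89))
  expect_equal(apply_bsv(typ, log(2), 0)$CL, 2 * 0.756)
  expect_equal(apply_bsv(typ, 0, log(3))$V, 3 * 4.89)
  expect_error(apply_bsv(typ, Inf), "finite")
})

test_that("residual-error forms apply and scale as specified", {
  prop <- residual_error("proportional", 0.319)
  addv <- residual_error("additive", 1.5)
  mixd <- residual_error("mixed", 0.2, 0.8)
  f <- c(2, 20)
  # zero draw returns the prediction for every form
  expect_equal(apply_residual(f, prop, 0), f)
  expect_equal(apply_residual(f, addv, 0), f)
  expect_equal(apply_residual(f, mixd, 0, 0), f)
  # proportional SD scales with the prediction: 0.319 * 20 = 6.38
  expect_equal(sqrt(residual_variance(20, prop)), 6.38)
  # degenerate mixed form reduces to proportional
  mix0 <- residual_error("mixed", 0.319, 0)
  expect_equal(residual_variance(f, mix0), residual_variance(f, prop))
  eps <- c(0.1, -0.2)
  expect_equal(apply_residual(f, mix0, eps, 0), apply_residual(f, prop, eps))
  expect_error(residual_error("proportional", -1), "sigma")
  expect_error(residual_error("additive", 1, 2), "mixed")
})

test_that("model specifications survive a JSON round trip", {
  tmp <- tempfile(fileext = ".json")
  for (nm in c("model1", "model2", "model3")) {
    m <- vanco_model(nm)
    write_pk_model(m, tmp)
    m2 <- read_pk_model(tmp)
    expect_equal(m2$theta, m$theta)
    expect_equal(m2$omega, m$omega)
    expect_equal(m2$error$sigma, m$error$sigma)
    cov <- data.frame(WT = 3.1, SCR = 22)
    expect_equal(typical_parameters(m2, cov), typical_parameters(m, cov))
  }
  unlink(tmp)
})
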