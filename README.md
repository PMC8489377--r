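# vancopk

Population pharmacokinetics of vancomycin in infants, stratified by renal
function.

Infants receiving intravenous vancomycin are monitored with sparse trough and
peak samples (TDM), and their drug clearance depends strongly on body weight
and renal function. This package implements, end to end, the analysis used to
build renal-function-stratified population PK models for infants aged 1–24
months: infants with normal renal function (Schwartz eGFR 30–86
ml/min/1.73 m²) are modelled separately from infants with augmented renal
clearance (eGFR ≥ 86), and both against a pooled whole-population model. It is
aimed at pharmacometricians and methods researchers who want a fully scripted,
testable re-implementation of this workflow — including the estimator itself —
rather than a wrapper around external estimation software.

## The model

Structural model: one compartment, first-order elimination, zero-order
infusion input. For an infusion of amount *D* over duration *T*, with
*k = CL/V*,

```
C(t) = (D/T)/CL * (1 - exp(-k*min(t - t0, T))) * exp(-k*max(t - t0 - T, 0))
```

and multi-dose profiles superpose. Between-subject variability is log-normal
(`P_i = TV(P) e^eta`, `eta ~ N(0, omega^2)`, on CL in the final models) and
residual error is proportional (`Y = F(1 + eps)`). The stratified covariate
models, available from the registry with their published estimates:

```
model1 (normal):  CL = 0.407 (WT/2.25)^1.24 exp(-0.533 SCR/27.1);  V = 1.86 (WT/2.25)^1.28
model2 (ARC):     CL = 0.756 (WT/4.6)^1.03;                        V = 4.89 (WT/4.6)^0.918
model3 (pooled):  CL = 0.707 (WT/3.45)^1.23 exp(-0.377 SCR/19);    V = 3.39 (WT/3.45)^1.29
```

(WT kg, SCR μmol/L, CL L/h, V L.) Estimation is first-order conditional
estimation with interaction in Laplace form, written from scratch: per-subject
conditional modes by a vectorised damped Newton step, the marginal −2
log-likelihood by Laplace expansion about the modes, and quasi-Newton outer
optimisation on transformed parameters. An adaptive Gauss–Hermite quadrature
oracle and a numerical ODE oracle back the estimator and the closed-form
kinetics in the test suite. Around the estimator sit maturation-model
screening, stepwise forward-addition (ΔOFV > 3.84) / backward-elimination
(ΔOFV < 10.83) covariate search, goodness-of-fit and CWRES diagnostics,
visual predictive checks, a nonparametric bootstrap, shrinkage, and
external-validation metrics (MPE/MPE%/MAE/MAE%/RMSE) with paired Wilcoxon
model comparison. A synthetic-cohort generator reproduces the study design
(40 mg/kg/day in 2–4 infusions ≥ 60 min, trough/peak around the fifth dose,
covariates matched to the published group summaries) so the whole pipeline is
exercised by simulation.

## Worked example

```r
library(vancopk)

cfg <- cohort_config(n = 24, group = "augmented", seed = 7)
dat <- simulate_cohort(cfg, vanco_model("model2"))   # synthetic ARC cohort
fit <- pkfit(dat, vanco_model("model2"))             # FOCE-I fit
fit
#> Population PK fit (FOCE-I), model: model2
#>   subjects: 24   observations: 48
#>   OFV: 261.444
#>   convergence: ok (relative convergence (4), 24 iterations)
#>   estimates:
#>     TVCL      TVV    CL_WT     V_WT omega_CL    sigma
#>   0.8132   5.3373   1.0253   1.3874   0.2720   0.3208
```

The cohort was simulated from the ARC model's published values (TVCL 0.756
L/h, TVV 4.89 L, allometric exponents 1.03/0.918, BSV-CL SD 0.312,
proportional sigma 0.319), and the 24-subject refit recovers them to within
the sampling noise of a cohort this small: typical clearance 0.81 L/h, volume
5.34 L, residual SD 0.32. `summary(fit)` adds shrinkage, `plot(fit)` draws the
four GOF panels, `vpc(fit)` and `bootstrap_pk(fit)` run the predictive check
and the bootstrap, and `gof_residuals(fit)` returns the CWRES table (here:
mean −0.03, SD 1.05 — calibrated, as expected for a correctly specified
model).

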