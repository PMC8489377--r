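---
title: "Population PK of vancomycin in infants: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population PK of vancomycin in infants: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vancopk)
```

## The problem

Vancomycin in infants is dosed by weight and adjusted by therapeutic drug
monitoring (TDM): typically one trough sample 30 minutes before the fifth
dose of a stable regimen and one peak sample shortly after the end of that
dose's infusion. Because renal elimination dominates, infants with augmented
renal clearance (ARC) behave differently from infants with normal renal
function, and pooling the two groups can blur which covariates matter.
`vancopk` implements the full analysis for renal-function-stratified
population PK modelling: a structural infusion model, stratified covariate
models, a nonlinear mixed-effects estimator, stepwise covariate selection,
and the standard diagnostic and validation toolkit, together with a
synthetic-cohort generator that emulates the study design so every stage can
be exercised and calibrated by simulation.

## Structural model

A one-compartment model with first-order elimination and zero-order
(infusion) input. For a single infusion of amount $D$ over duration $T$
starting at $t_0$, with clearance $CL$ (L/h), volume $V$ (L) and
$k = CL/V$:

$$C(t) = \frac{D/T}{CL}\left(1 - e^{-k \min(t - t_0,\,T)}\right)
         e^{-k \max(t - t_0 - T,\,0)}, \qquad t > t_0,$$

and multi-dose profiles are the superposition of single-dose profiles (the
system is linear; overlapping infusion rates add). All times are hours,
amounts mg, concentrations mg/L. We deliberately superpose from the first
dose rather than assuming steady state, because TDM samples are anchored to
the fifth dose, not to steady state. An independent numerical reference
(`ode_oracle_concentration()`, segment-wise `deSolve::lsoda` with piecewise
constant input) backs the closed form in the test suite at $10^{-6}$
relative agreement.

## Covariate models

Renal function is classified by the modified Schwartz formula
$eGFR = 88.4\,k\,HT/SCR$ ($k$ = 0.33 preterm < 1 y, 0.45 term < 1 y, 0.55
children). Infants with $30 \le eGFR < 86$ ml/min/1.73 m$^2$ form the
normal-renal-function group, $eGFR \ge 86$ the ARC group, and below 30 is an
exclusion. The Schwartz age classes leave a gap between 12 and 24 months;
the cohort generator assigns the child coefficient (0.55) from 12 months on.

The three registry models (`vanco_model("model1" | "model2" | "model3")`)
carry the published structure and estimates:

* model1 (normal): $CL = \theta_1 (WT/2.25)^{\theta_3} e^{\theta_5 SCR/27.1}$,
  $V = \theta_2 (WT/2.25)^{\theta_4}$
* model2 (ARC): $CL = \theta_1 (WT/4.6)^{\theta_3}$,
  $V = \theta_2 (WT/4.6)^{\theta_4}$
* model3 (pooled): as model1 with medians 3.45 kg and 19 μmol/L.

Two modelling conventions deserve emphasis. First, the serum-creatinine
factor is the *estimable* form $e^{\theta_5 SCR/SCR_{med}}$, which is not
unity at the median; the typical clearance at the median therefore includes
the factor $e^{\theta_5}$. Second, between-subject variability is log-normal
($P_i = TV(P)\,e^{\eta_i}$, $\eta_i \sim N(0, \omega^2)$) on CL only in the
final models, matching their published variance structure; the engine also
supports an $\eta$ on V for base-model exploration. Residual error supports
additive, proportional ($Y = F(1+\varepsilon)$) and mixed forms; the final
models are proportional.

Maturation screening offers the five standard structures: free allometric
exponents (I), fixed 0.75/1 exponents (II), a sigmoid age maturation factor
$MF = Age^{Hill}/(TM_{50}^{Hill} + Age^{Hill})$ on top of fixed allometry
(III), and a bodyweight- or age-dependent sigmoid decline of the allometric
exponent itself (IV, V). Form III is implemented as the *increasing* sigmoid
with $MF(TM_{50}) = 0.5$, the conventional reading of this maturation
factor; ages are months throughout.

## Estimation: FOCE with interaction, Laplace form

The marginal likelihood of each subject integrates the conditional Gaussian
observation density over the random effect. We approximate it by expanding
about the conditional mode $\hat\eta_i$ (empirical Bayes estimate): with
$q_i(\eta) = -2\log p(y_i \mid \eta) - 2 \log p(\eta)$,

$$-2\log L_i \approx q_i(\hat\eta_i) - d\log(4\pi) + \log\det q_i''(\hat\eta_i),$$

summed over subjects to give the objective function value (OFV). The full
conditional curvature is used, so the $\eta$–$\varepsilon$ interaction of
the proportional error model (residual SD proportional to the
$\eta$-dependent prediction) is retained — the behaviour one wants for this
error model. All $\log 2\pi$ constants are kept, so absolute OFVs differ
from other tools by a design-fixed constant; only OFV *differences* drive
selection decisions, which is the invariant that matters.

Numerics: the inner problem is solved for all subjects simultaneously by a
damped Newton iteration on the vectorised conditional objective
(finite-difference derivatives, step $10^{-4}$; gradient tolerance
$10^{-8}$; cold start at $\eta = 0$ for bitwise reproducibility; steps capped
at 3 with vectorised backtracking). The outer optimisation runs `nlminb` on
transformed parameters ($\log$ for TVCL, TVV, variance components and other
positive parameters; identity for exponents and slopes), relative tolerance
$10^{-8}$, with up to two cheap restarts from the found point when the
optimiser's convergence code is not clean. Estimation is deterministic given
data and starting values; all randomness lives in data simulation. An
adaptive Gauss–Hermite quadrature reference (`ofv_quadrature_oracle()`,
nodes centred at $\hat\eta_i$ and scaled by the Laplace SD) provides the
accuracy contract: within 1 OFV unit on small cohorts in the test suite.

Shrinkage follows the usual EBE diagnostics:
$\eta$-shrinkage $= 100(1 - SD(\hat\eta)/\hat\omega)$ and
$\varepsilon$-shrinkage $= 100(1 - SD(IWRES))$ with
$IWRES = (y - IPRED)/(\hat\sigma\, IPRED)$ for the proportional form.

## Covariate selection

`forward_search()` / `backward_elimination()` implement the stepwise
procedure: a candidate is admitted when it lowers the OFV by more than 3.84
($\chi^2_1$, $p<0.05$) — the best drop first when several qualify — and an
in-model covariate is removed again when its exclusion raises the OFV by
less than 10.83 ($\chi^2_1$, $p<0.001$), weakest first. Candidates enter
clearance as centred exponential-slope terms (binary flags as
$e^{\theta x}$); weight scales both CL and V. The engine is driven by an
*OFV oracle* — any function from a covariate set to a minimised OFV — so the
same code runs against the real FOCE estimator or against a table of
recorded OFVs. A shipped fixture with the published search's OFVs lets the
tests replay every decision of that search deterministically, which
separates the correctness of the decision logic from the behaviour of the
estimator. Candidates whose oracle evaluation fails are skipped with a
warning, never silently admitted.

## The synthetic-cohort generator

`cohort_config()` + `simulate_cohort()` emulate the study conditions:

* dosing 40 mg/kg/day — read as a *total daily* dose (the printed group
  median daily doses, e.g. 145 mg/d at a median weight of 3.3 kg, are only
  consistent with the daily reading) — split evenly into 2–4 infusions of
  1 h (the protocol minimum) at q12/q8/q6 h; six doses are generated;
* one trough 0.5 h before dose 5 and one peak 0.5 h after the *end* of the
  dose-5 infusion (the standard vancomycin TDM convention; the anchor of
  the peak is configurable);
* weight and serum creatinine are log-normal, truncated to the printed group
  ranges, with the log-mean calibrated so that the *truncated* median equals
  the printed group median (the printed summaries describe the observed,
  i.e. truncated, samples) and log-SDs taken from the printed mean/median
  ratios (range-based where mean ≈ median);
* height follows a weight-allometric relation with noise, sampled from the
  interval that places the Schwartz eGFR inside the configured group's band;
  draws for which no admissible height exists are rejected and creatinine
  redrawn. This enforces group membership exactly while preserving the
  printed weight and creatinine summaries, at the cost of mild distortion of
  the height distribution — an acceptable trade because height enters the
  analysis only through eGFR;
* age is 1 month plus a discretised exponential (median 1 month, capped at
  24), preterm status, sex and comedication are Bernoulli at the printed
  group frequencies, and auxiliary labs (ALT, AST, BUN, CYSC, ALB, TP) are
  independent truncated log-normals around the printed medians — they exist
  to exercise covariate screening, not to model physiology;
* concentrations are simulated with log-normal BSV on CL and the model's
  residual error; covariates are constant within a subject and each
  synthetic subject belongs to exactly one renal-function group (the
  study's double counting of patients with fluctuating renal function is
  not modelled).

What the generator does *not* emulate: correlation among labs, time-varying
renal function, dose adjustments after TDM, repeated TDM occasions (the real
study averaged ~2.4 observations per subject; the generator produces exactly
one trough and one peak), disease types, and assay quantification limits.
Calibration results on these cohorts therefore demonstrate the internal
consistency of the pipeline under its own assumptions, not the behaviour of
the method on hospital data.

```{r example, eval = FALSE}
cfg <- cohort_config(n = 64, group = "augmented", seed = 1)
dat <- simulate_cohort(cfg, vanco_model("model2"))
fit <- pkfit(dat, vanco_model("model2"))
summary(fit)
plot(fit)                      # GOF panels
vpc(fit, n_sim = 200, seed = 1)
bootstrap_pk(fit, n_reps = 100, seed = 1)
```

## Diagnostics and validation

* **GOF / CWRES** (`gof_residuals()`): population and individual
  predictions plus conditional weighted residuals from the FOCE
  linearisation — each subject's residual vector about
  $F(\hat\eta) - G\hat\eta$ is decorrelated by
  $G\Omega G^\top + V(F(\hat\eta))$, $G = \partial F/\partial \eta$ at the
  mode. On data simulated from the fitted model CWRES should have mean ≈ 0
  and SD ≈ 1, which the suite asserts.
* **VPC** (`vpc()`): replicate datasets simulated under the design; observed
  5/50/95th percentiles per bin against the simulated percentile
  distribution with 95% CIs. Bins default to the two nominal sample classes
  (trough vs peak) because the design has exactly two time classes; numeric
  time breaks are available for richer designs.
* **Bootstrap** (`bootstrap_pk()`): subjects resampled with replacement to
  the original cohort size, each replicate refit from the point estimate;
  medians, 2.5–97.5% percentile intervals, bias%
  $=100(\mathrm{median}-\mathrm{estimate})/\mathrm{estimate}$ (denominator:
  the original point estimate) and the success rate. A replicate counts as
  failed when the optimiser hits its budget or the objective is not finite;
  a flat-region stall at a finite optimum counts as success.
* **External validation** (`external_validation()`): Bayesian forecasting —
  random effects set to their conditional modes given *all* of a subject's
  observations with population parameters fixed — followed by the five
  standard metrics (MPE, MPE%, MAE, MAE%, RMSE). Two models on the same
  observations are compared by a two-sided Wilcoxon signed-rank test on the
  paired absolute prediction errors (`compare_models_paired()`).

## Problem sizes and reproducibility

The simulation studies use the study-scale designs: 61 subjects
(normal-renal-function model), 64 (ARC model) and 115 (pooled model), two
observations per subject; recovery experiments use 10 replicate cohorts,
the bootstrap 100 resamples, and VPCs 200 simulated replicates — sizes at
which the Monte-Carlo error of the reported medians is small relative to
the published bootstrap intervals. Every stochastic stage takes an explicit
seed, cohorts are bit-reproducible functions of their seed, and estimation
is deterministic, so any number in a report can be regenerated exactly.

## Known limitations

One-compartment kinetics only (no two-compartment distribution phase);
no SAEM or full Bayesian estimation; no interoccasion variability;
single-level (diagonal) random effects; shrinkage and recovery results on
two-sample-per-subject designs are inherently noisy — single-cohort
$\eta$-shrinkage estimates vary by several percentage points across seeds;
and the selection engine searches clearance covariates one at a time, as
the stepwise procedure prescribes, so it inherits the usual caveats of
stepwise selection.
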