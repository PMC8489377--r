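## ---------------------------------------------------------------------------
## Synthetic infant cohorts emulating the vancomycin TDM study design.
## ---------------------------------------------------------------------------

# Run expr with a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Log-normal draws truncated to a printed range, with the log-mean calibrated
# so the TRUNCATED distribution's median equals the printed median (the
# printed summaries describe the observed, i.e. truncated, sample).
rlnorm_trunc <- function(n, median, sdlog, lower, upper) {
  med_gap <- function(ml) {
    pa <- stats::plnorm(lower, ml, sdlog)
    pb <- stats::plnorm(upper, ml, sdlog)
    stats::qlnorm((pa + pb) / 2, ml, sdlog) - median
  }
  ml <- stats::uniroot(med_gap, interval = log(median) + c(-2, 2),
                       extendInt = "yes", tol = 1e-10)$root
  pa <- stats::plnorm(lower, ml, sdlog)
  pb <- stats::plnorm(upper, ml, sdlog)
  stats::qlnorm(stats::runif(n, pa, pb), ml, sdlog)
}

# Covariate location/spread targets of the two modelling groups (medians and
# ranges as summarised for the study population; sdlog for right-skewed
# positive covariates chosen from the printed mean/median ratio where the mean
# is informative, otherwise from the printed range).
group_targets <- function(group) {
  switch(group,
    normal = list(
      wt  = list(median = 2.25, sdlog = sqrt(2 * log(2.86 / 2.25)),
                 range = c(1.15, 13)),
      scr = list(median = 27.1, sdlog = sqrt(2 * log(30.80 / 27.1)),
                 range = c(14, 315)),
      ht  = list(median = 44, exponent = 0.4, sdlog = 0.06, range = c(32, 90)),
      age_mean_excess = 1.31, age_max = 24,
      preterm = 29 / 61, male = 37 / 61, comed = 47 / 61,
      labs = list(ALT = c(19.5, 2, 858), AST = c(36, 7, 2949),
                  BUN = c(3.44, 0.7, 52), CYSC = c(1.51, 0.03, 3.18),
                  ALB = c(31.35, 7.1, 58.1), TP = c(46.9, 10, 83.1))),
    augmented = list(
      wt  = list(median = 4.60, sdlog = sqrt(2 * log(5.34 / 4.60)),
                 range = c(2.2, 14)),
      scr = list(median = 16.8, sdlog = log(29 / 8) / 5, range = c(8, 29)),
      ht  = list(median = 54, exponent = 0.4, sdlog = 0.06, range = c(42.9, 110)),
      age_mean_excess = 2.36, age_max = 24,
      preterm = 17 / 64, male = 41 / 64, comed = 54 / 64,
      labs = list(ALT = c(30, 6, 722), AST = c(40, 11.1, 751),
                  BUN = c(2.8, 0.4, 8.3), CYSC = c(1.37, 0.02, 2.63),
                  ALB = c(35.1, 27.7, 44.1), TP = c(55.1, 40.2, 72.1))),
    stop("unknown group '", group, "'"))
}

#' Configuration of a synthetic infant cohort
#'
#' Describes a virtual cohort emulating the study design: infants aged 1--24
#' months dosed 40 mg/kg/day of vancomycin split into 2--4 infusions of at
#' least 60 min, with one trough sample 30 min before the fifth dose and one
#' peak sample 30 min after the end of the fifth infusion. Covariate
#' distributions are matched to the renal-function group summaries
#' (`"normal"`: eGFR 30--86 ml/min/1.73 m^2; `"augmented"`: eGFR >= 86;
#' `"mixed"`: both, in the study's 61:64 proportion).
#'
#' @param n number of subjects (>= 1).
#' @param group `"normal"`, `"augmented"`, or `"mixed"`.
#' @param seed integer seed controlling all randomness of the cohort.
#' @param mg_per_kg_day total daily dose (mg/kg/day).
#' @param splits admissible numbers of daily infusions (subset of 2:4; one is
#'   drawn per subject).
#' @param infusion_duration infusion length (h).
#' @param n_doses number of doses generated (>= anchor dose).
#' @param anchor_dose index of the dose around which TDM samples are drawn.
#' @param trough_offset time before the anchor dose start for the trough (h).
#' @param peak_offset time after the anchor infusion end for the peak (h).
#' @return An object of class `"cohort_config"`.
#' @export
cohort_config <- function(n, group = c("normal", "augmented", "mixed"),
                          seed = 1L, mg_per_kg_day = 40, splits = 2:4,
                          infusion_duration = 1, n_doses = 6L,
                          anchor_dose = 5L, trough_offset = 0.5,
                          peak_offset = 0.5) {
  group <- match.arg(group)
  if (n < 1) stop("n must be >= 1")
  if (!all(splits %in% 2:4) || length(splits) == 0L)
    stop("splits must be a non-empty subset of 2:4")
  if (trough_offset <= 0 || peak_offset <= 0) stop("offsets must be positive")
  if (infusion_duration <= 0) stop("infusion duration must be positive")
  if (n_doses < anchor_dose) stop("n_doses must cover the anchor dose")
  structure(list(n = as.integer(n), group = group, seed = as.integer(seed),
                 mg_per_kg_day = mg_per_kg_day, splits = splits,
                 infusion_duration = infusion_duration,
                 n_doses = as.integer(n_doses),
                 anchor_dose = as.integer(anchor_dose),
                 trough_offset = trough_offset, peak_offset = peak_offset),
            class = "cohort_config")
}

#' Draw subject covariates for a cohort
#'
#' Samples weight, serum creatinine, height, age, preterm status, sex,
#' auxiliary labs and comedication matched to the renal-function group
#' summaries. Weight and creatinine are truncated log-normals matched to the
#' group medians; height follows a weight-allometric relation with noise,
#' truncated so that the Schwartz eGFR lands in the configured group's band
#' (draws for which no admissible height exists are rejected and creatinine
#' redrawn). Uses the current RNG stream; seed control sits in
#' [simulate_cohort()].
#'
#' @param config a [cohort_config()].
#' @return data.frame with one row per subject: `WT`, `HT`, `SCR`, `AGE`
#'   (months), `PRETERM`, `SEX` (1 = male), `ALT`, `AST`, `BUN`, `CYSC`,
#'   `ALB`, `TP`, `COMED`, `EGFR`, `GROUP`.
#' @export
sample_covariates <- function(config) {
  n <- config$n
  grp <- if (config$group == "mixed") {
    sample(c("normal", "augmented"), n, TRUE, prob = c(61, 64))
  } else rep(config$group, n)
  out <- vector("list", 2L)
  for (g in unique(grp)) {
    idx <- which(grp == g)
    tg <- group_targets(g)
    m <- length(idx)
    preterm <- as.integer(stats::runif(m) < tg$preterm)
    age <- pmin(1 + floor(stats::rexp(m, 1 / tg$age_mean_excess)), tg$age_max)
    k <- ifelse(age < 12, ifelse(preterm == 1, 0.33, 0.45), 0.55)
    wt <- rlnorm_trunc(m, tg$wt$median, tg$wt$sdlog,
                       tg$wt$range[1], tg$wt$range[2])
    scr <- ht <- rep(NA_real_, m)
    todo <- seq_len(m)
    for (attempt in 1:200) {
      if (length(todo) == 0L) break
      s <- rlnorm_trunc(length(todo), tg$scr$median, tg$scr$sdlog,
                        tg$scr$range[1], tg$scr$range[2])
      # admissible height interval for the group's eGFR band
      lo_g <- if (g == "normal") 30 * s / (88.4 * k[todo]) else
        86 * s / (88.4 * k[todo])
      hi_g <- if (g == "normal") 86 * s / (88.4 * k[todo]) else
        rep(Inf, length(todo))
      lo <- pmax(lo_g, tg$ht$range[1])
      hi <- pmin(hi_g, tg$ht$range[2])
      ml <- log(tg$ht$median) +
        tg$ht$exponent * (log(wt[todo]) - log(tg$wt$median))
      pa <- stats::plnorm(lo, ml, tg$ht$sdlog)
      pb <- stats::plnorm(hi, ml, tg$ht$sdlog)
      ok <- (pb - pa) > 1e-4
      if (any(ok)) {
        u <- stats::runif(sum(ok), pa[ok], pb[ok])
        hh <- stats::qlnorm(u, ml[ok], tg$ht$sdlog)
        # keep strictly inside the band (guards the open upper boundary)
        hh <- pmin(pmax(hh, lo[ok] * (1 + 1e-9)), hi[ok] * (1 - 1e-9))
        scr[todo[ok]] <- s[ok]
        ht[todo[ok]] <- hh
      }
      todo <- todo[!ok]
    }
    if (length(todo) > 0L)
      stop("cohort generation failed: no admissible covariates for ",
           length(todo), " subject(s) in group '", g, "'")
    egfr <- 88.4 * k * ht / scr
    lab <- lapply(tg$labs, function(p)
      rlnorm_trunc(m, p[1], log(p[3] / p[2]) / 5.4, p[2], p[3]))
    out[[match(g, unique(grp))]] <- data.frame(
      idx = idx, WT = wt, HT = ht, SCR = scr, AGE = age, PRETERM = preterm,
      SEX = as.integer(stats::runif(m) < tg$male),
      ALT = lab$ALT, AST = lab$AST, BUN = lab$BUN, CYSC = lab$CYSC,
      ALB = lab$ALB, TP = lab$TP,
      COMED = as.integer(stats::runif(m) < tg$comed),
      EGFR = egfr, GROUP = g)
  }
  res <- do.call(rbind, out)
  res <- res[order(res$idx), setdiff(names(res), "idx"), drop = FALSE]
  rownames(res) <- NULL
  stopifnot(all(as.character(classify_renal_function(res$EGFR)) == res$GROUP))
  res
}

#' Weight-based dosing regimen
#'
#' Total daily dose `mg_per_kg_day * WT`, split evenly into the subject's
#' number of daily infusions at equal intervals (q12/q8/q6 h for 2/3/4
#' splits).
#'
#' @param wt body weight (kg).
#' @param splits number of infusions per day (2, 3 or 4).
#' @param config a [cohort_config()].
#' @return A [dosing_events()] table with `config$n_doses` rows.
#' @export
build_dosing_regimen <- function(wt, splits, config) {
  if (!splits %in% 2:4) stop("splits must be 2, 3 or 4")
  tau <- 24 / splits
  dosing_events(start_time = tau * (seq_len(config$n_doses) - 1L),
                amount = config$mg_per_kg_day * wt / splits,
                duration = config$infusion_duration)
}

#' TDM sampling times around the anchor dose
#'
#' One trough `trough_offset` h before the start of the anchor (fifth) dose
#' and one peak `peak_offset` h after the end of the anchor infusion.
#'
#' @param regimen a [dosing_events()] table.
#' @param config a [cohort_config()].
#' @return data.frame with columns `time` (h) and `kind`
#'   (`"trough"`/`"peak"`).
#' @export
schedule_tdm_samples <- function(regimen, config) {
  a <- config$anchor_dose
  if (nrow(regimen) < a)
    stop("regimen has ", nrow(regimen), " doses; at least ", a, " required")
  t_tr <- regimen$start_time[a] - config$trough_offset
  t_pk <- regimen$start_time[a] + regimen$duration[a] + config$peak_offset
  data.frame(time = c(t_tr, t_pk), kind = c("trough", "peak"))
}

#' Simulate a full cohort dataset
#'
#' Generates covariates, dosing and TDM sampling per [cohort_config()], then
#' simulates concentrations under the covariate model: per-subject random
#' effects eta ~ N(0, omega^2) on the log scale, closed-form superposition
#' predictions at the scheduled times, and the model's residual-error draw.
#' Fully reproducible: the dataset is a deterministic function of
#' `config$seed`.
#'
#' @param config a [cohort_config()].
#' @param model a [pk_model()] supplying theta, omega and the residual error.
#' @return An event-table data.frame (see [read_pkdata()]) with one dose row
#'   per infusion and one observation row per sample; negative post-noise
#'   observations are possible and their fraction is recorded in the
#'   `"negative_dv_fraction"` attribute.
#' @examples
#' dat <- simulate_cohort(cohort_config(4, "augmented", seed = 1),
#'                        vanco_model("model2"))
#' head(dat)
#' @export
simulate_cohort <- function(config, model) {
  with_seed(config$seed, {
    cov <- sample_covariates(config)
    splits <- sample(rep(config$splits, 2L), config$n, replace = TRUE)
    typ <- typical_parameters(model, cov)
    eta_cl <- stats::rnorm(config$n, 0,
                           if ("CL" %in% names(model$omega)) model$omega[["CL"]] else 0)
    eta_v <- stats::rnorm(config$n, 0,
                          if ("V" %in% names(model$omega)) model$omega[["V"]] else 0)
    ind <- apply_bsv(typ, eta_cl, eta_v)
    rows <- vector("list", config$n)
    for (i in seq_len(config$n)) {
      reg <- build_dosing_regimen(cov$WT[i], splits[i], config)
      smp <- schedule_tdm_samples(reg, config)
      f <- concentration_at(smp$time, reg, ind$CL[i], ind$V[i])
      eps <- stats::rnorm(nrow(smp), 0, model$error$sigma)
      eps2 <- if (model$error$form == "mixed")
        stats::rnorm(nrow(smp), 0, model$error$sigma2) else 0
      dv <- apply_residual(f, model$error, eps, eps2)
      di <- data.frame(ID = i,
                       TIME = c(reg$start_time, smp$time),
                       EVID = c(rep(1L, nrow(reg)), rep(0L, nrow(smp))),
                       AMT = c(reg$amount, rep(NA_real_, nrow(smp))),
                       DUR = c(reg$duration, rep(NA_real_, nrow(smp))),
                       DV = c(rep(NA_real_, nrow(reg)), dv),
                       MDV = c(rep(1L, nrow(reg)), rep(0L, nrow(smp))),
                       KIND = c(rep(NA_character_, nrow(reg)), smp$kind))
      rows[[i]] <- cbind(di, cov[rep(i, nrow(di)), , drop = FALSE],
                         row.names = NULL)
    }
    out <- do.call(rbind, rows)
    out <- validate_pkdata(out)
    neg <- mean(out$DV[out$EVID == 0] < 0)
    if (neg > 0)
      message("simulate_cohort: ", signif(100 * neg, 3),
              "% of simulated observations are negative")
    attr(out, "negative_dv_fraction") <- neg
    attr(out, "individual_params") <-
      data.frame(ID = seq_len(config$n), CL = ind$CL, V = ind$V,
                 TVCL = typ$CL, TVV = typ$V,
                 eta_CL = eta_cl, eta_V = eta_v)
    out
  })
}
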