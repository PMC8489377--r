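## ---------------------------------------------------------------------------
## Goodness of fit, visual predictive check, bootstrap, external validation.
## ---------------------------------------------------------------------------

#' Goodness-of-fit table with conditional weighted residuals
#'
#' Per observation: DV, population prediction PRED (random effects at 0),
#' individual prediction IPRED (at the empirical Bayes estimates), and CWRES
#' from the FOCE linearisation: per subject the residual
#' \eqn{y - (F(\hat\eta) - G\hat\eta)} is decorrelated by the approximate
#' marginal covariance \eqn{G \Omega G^\top + V(F(\hat\eta))}, with
#' \eqn{G = \partial F/\partial\eta} at the mode. Subjects whose marginal
#' covariance is numerically singular fall back to IWRES with a warning.
#'
#' @param fit a [pkfit()] result.
#' @return data.frame with columns `ID`, `time`, `kind`, `DV`, `PRED`,
#'   `IPRED`, `IWRES`, `CWRES`.
#' @export
gof_residuals <- function(fit) {
  design <- fit$design
  typ <- typical_parameters(fit$model, design$cov)
  pred <- design_pred(design, typ$CL, typ$V)
  ipred <- fitted_conc(fit, individual = TRUE)
  iwres <- (design$y - ipred) / sqrt(residual_variance(ipred, fit$error))
  edim <- colnames(fit$eta)
  d <- length(edim)
  cwres <- numeric(design$nobs)
  if (d == 0L) {
    cwres <- (design$y - pred) / sqrt(residual_variance(pred, fit$error))
  } else {
    omega <- diag(fit$omega[edim]^2, d)
    h <- 1e-4
    fallback <- FALSE
    for (i in seq_len(design$n)) {
      sel <- design$obs_sid == i
      eta_i <- fit$eta[i, , drop = FALSE]
      f_at <- function(eta_row) {
        e_full <- matrix(0, design$n, d)
        e_full[i, ] <- eta_row
        ip <- ind_params(typ, e_full, edim)
        design_pred(design, ip$cl, ip$v)[sel]
      }
      f0 <- f_at(eta_i)
      G <- matrix(0, sum(sel), d)
      for (j in seq_len(d)) {
        ej <- eta_i; ej[j] <- ej[j] + h
        em <- eta_i; em[j] <- em[j] - h
        G[, j] <- (f_at(ej) - f_at(em)) / (2 * h)
      }
      covm <- G %*% omega %*% t(G) +
        diag(residual_variance(f0, fit$error), sum(sel))
      ey <- f0 - as.vector(G %*% t(eta_i))
      ch <- tryCatch(chol(covm), error = function(e) NULL)
      if (is.null(ch)) {
        cwres[sel] <- iwres[sel]
        fallback <- TRUE
      } else {
        cwres[sel] <- backsolve(ch, design$y[sel] - ey, transpose = TRUE)
      }
    }
    if (fallback)
      warning("singular marginal covariance for some subject(s); IWRES used")
  }
  data.frame(ID = design$ids[design$obs_sid], time = design$obs_time,
             kind = design$kind, DV = design$y, PRED = pred, IPRED = ipred,
             IWRES = iwres, CWRES = cwres)
}

# Simulate replicate observation vectors under the fitted design.
simulate_dv <- function(design, model, nsim) {
  typ <- typical_parameters(model, design$cov)
  edim <- names(model$omega)
  out <- matrix(NA_real_, design$nobs, nsim)
  for (s in seq_len(nsim)) {
    eta <- vapply(model$omega, function(o) stats::rnorm(design$n, 0, o),
                  numeric(design$n))
    eta <- matrix(eta, nrow = design$n)
    ip <- ind_params(typ, eta, edim)
    f <- design_pred(design, ip$cl, ip$v)
    eps <- stats::rnorm(design$nobs, 0, model$error$sigma)
    eps2 <- if (model$error$form == "mixed")
      stats::rnorm(design$nobs, 0, model$error$sigma2) else 0
    out[, s] <- apply_residual(f, model$error, eps, eps2)
  }
  out
}

#' Visual predictive check
#'
#' Simulates `n_sim` replicates of the dataset under the model (same subjects,
#' dosing and sampling times) and compares observed 5th/50th/95th percentiles
#' per bin with the distribution of the same percentiles across replicates
#' (median and 95% CI). By default the two nominal sample classes of the TDM
#' design (trough vs peak) define the bins; numeric time breaks can be given
#' instead for richer designs.
#'
#' @param fit a [pkfit()] result (or a model evaluated at fixed parameters via
#'   `pkfit`-free use: pass any object with `design` and `model`).
#' @param n_sim number of simulated replicates (>= 100).
#' @param seed seed for the simulation.
#' @param bins `"kind"` or a numeric vector of time breakpoints.
#' @param pi_probs percentiles defining the prediction band (default 5/50/95).
#' @return An object of class `"pk_vpc"`: per-bin table of observed and
#'   simulated percentiles with CIs, and the fraction of observations inside
#'   the simulated 90% prediction interval (`coverage`). Empty bins are
#'   dropped with a warning.
#' @export
vpc <- function(fit, n_sim = 200L, seed = 1L, bins = "kind",
                pi_probs = c(0.05, 0.5, 0.95)) {
  if (n_sim < 100L) stop("n_sim must be >= 100")
  design <- fit$design
  if (identical(bins, "kind")) {
    bin_id <- design$kind
    if (anyNA(bin_id)) {
      bin_id <- as.character(cut(design$obs_time, breaks = 4))
    }
  } else {
    bin_id <- as.character(cut(design$obs_time, breaks = bins,
                               include.lowest = TRUE))
    if (anyNA(bin_id)) {
      warning("observations outside the bin breaks were dropped")
    }
  }
  keep <- !is.na(bin_id)
  sims <- with_seed(seed, simulate_dv(design, fit$model, n_sim))
  ub <- unique(bin_id[keep])
  rows <- list()
  lo <- numeric(design$nobs); hi <- numeric(design$nobs)
  for (b in ub) {
    sel <- keep & bin_id == b
    obs_q <- stats::quantile(design$y[sel], pi_probs, names = FALSE)
    sim_q <- apply(sims[sel, , drop = FALSE], 2L, stats::quantile,
                   probs = pi_probs, names = FALSE)
    med <- apply(sim_q, 1L, stats::median)
    ci_l <- apply(sim_q, 1L, stats::quantile, probs = 0.025, names = FALSE)
    ci_u <- apply(sim_q, 1L, stats::quantile, probs = 0.975, names = FALSE)
    rows[[b]] <- data.frame(bin = b, percentile = 100 * pi_probs,
                            observed = obs_q, simulated = med,
                            ci_lower = ci_l, ci_upper = ci_u,
                            n_obs = sum(sel))
    lo[sel] <- med[1L]
    hi[sel] <- med[length(pi_probs)]
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  coverage <- mean(design$y[keep] >= lo[keep] & design$y[keep] <= hi[keep])
  structure(list(table = tab, coverage = coverage, n_sim = n_sim,
                 pi_probs = pi_probs),
            class = "pk_vpc")
}

#' @export
print.pk_vpc <- function(x, ...) {
  cat("Visual predictive check (", x$n_sim, " replicates)\n", sep = "")
  print(x$table, row.names = FALSE, digits = 4)
  cat("fraction of observations inside the ",
      round(100 * (max(x$pi_probs) - min(x$pi_probs))),
      "% PI: ", round(100 * x$coverage, 1), "%\n", sep = "")
  invisible(x)
}

#' @export
plot.pk_vpc <- function(x, ...) {
  tab <- x$table
  bins <- unique(tab$bin)
  at <- seq_along(bins)
  ylim <- range(tab$observed, tab$ci_lower, tab$ci_upper)
  graphics::plot(NA, xlim = c(0.5, length(bins) + 0.5), ylim = ylim,
                 xaxt = "n", xlab = "bin", ylab = "concentration (mg/L)",
                 main = "Visual predictive check", ...)
  graphics::axis(1, at = at, labels = bins)
  for (i in at) {
    tb <- tab[tab$bin == bins[i], ]
    for (j in seq_len(nrow(tb))) {
      graphics::rect(i - 0.3, tb$ci_lower[j], i + 0.3, tb$ci_upper[j],
                     col = grDevices::adjustcolor("steelblue", 0.25),
                     border = NA)
      graphics::segments(i - 0.3, tb$simulated[j], i + 0.3, tb$simulated[j],
                         col = "steelblue", lwd = 2)
      graphics::points(i, tb$observed[j], pch = 19)
    }
  }
  invisible(x)
}

#' Nonparametric bootstrap of a population fit
#'
#' Resamples subjects with replacement to the original cohort size, refits
#' each replicate starting from the point estimates, and summarises each
#' parameter by its bootstrap median, 2.5--97.5% percentile interval and
#' relative bias \eqn{100 (\mathrm{median} - \mathrm{estimate})/\mathrm{estimate}}.
#' Replicates that fail to converge are excluded from the percentiles and
#' reflected in the success rate.
#'
#' @param fit a [pkfit()] result.
#' @param n_reps number of bootstrap replicates (>= 50 recommended for
#'   reporting).
#' @param seed seed controlling the resampling.
#' @param control passed to the replicate fits.
#' @return An object of class `"pkboot"`: `table` (parameter, estimate,
#'   median, lower, upper, bias_pct), `success_rate` (%), `n_reps`.
#' @export
bootstrap_pk <- function(fit, n_reps = 200L, seed = 1L,
                         control = pkfit_control()) {
  est <- coef(fit)
  design <- fit$design
  reps <- with_seed(seed, {
    lapply(seq_len(n_reps), function(r) {
      take <- sample(design$ids, design$n, replace = TRUE)
      pieces <- lapply(seq_along(take), function(i) {
        di <- design$data[design$data$ID == take[i], , drop = FALSE]
        di$ID <- i
        di
      })
      bd <- do.call(rbind, pieces)
      ft <- tryCatch(suppressWarnings(pkfit(bd, fit$model, control = control)),
                     error = function(e) NULL)
      # a replicate counts as converged when the optimiser reports success or
      # stalls in a flat region at a finite optimum; hitting the iteration
      # budget or a non-finite objective is a failure
      ok <- !is.null(ft) && is.finite(ft$ofv) &&
        (ft$convergence == 0 || grepl("false convergence", ft$message))
      if (!ok) return(NULL)
      coef(ft)
    })
  })
  ok <- !vapply(reps, is.null, logical(1))
  if (!any(ok)) stop("no bootstrap replicate converged")
  mat <- do.call(rbind, reps[ok])
  med <- apply(mat, 2L, stats::median)
  lo <- apply(mat, 2L, stats::quantile, probs = 0.025, names = FALSE)
  hi <- apply(mat, 2L, stats::quantile, probs = 0.975, names = FALSE)
  tab <- data.frame(parameter = names(est), estimate = unname(est),
                    boot_median = unname(med[names(est)]),
                    lower = unname(lo[names(est)]),
                    upper = unname(hi[names(est)]),
                    bias_pct = unname(100 * (med[names(est)] - est) / est))
  structure(list(table = tab, success_rate = 100 * mean(ok),
                 n_reps = n_reps),
            class = "pkboot")
}

#' @export
print.pkboot <- function(x, ...) {
  cat("Nonparametric bootstrap (", x$n_reps, " replicates, success rate ",
      round(x$success_rate, 1), "%)\n", sep = "")
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Prediction-error metrics
#'
#' The five standard external-validation metrics between individual-predicted
#' and observed concentrations:
#' \eqn{MPE = \frac{1}{n}\sum (C_{IPRED} - C_{OBS})},
#' \eqn{MAE = \frac{1}{n}\sum |C_{IPRED} - C_{OBS}|},
#' \eqn{MPE\% = \frac{100}{n}\sum (C_{IPRED} - C_{OBS})/C_{OBS}},
#' \eqn{MAE\% = \frac{100}{n}\sum |(C_{IPRED} - C_{OBS})/C_{OBS}|},
#' \eqn{RMSE = \sqrt{\frac{1}{n}\sum (C_{IPRED} - C_{OBS})^2}}.
#' Observations equal to zero are excluded from the relative metrics.
#'
#' @param ipred individual predictions (mg/L).
#' @param obs observations (mg/L), same length.
#' @return named list: `MPE`, `MAE` (mg/L), `MPE_pct`, `MAE_pct` (%),
#'   `RMSE` (mg/L), `n`, `n_excluded_relative`.
#' @export
prediction_metrics <- function(ipred, obs) {
  if (length(ipred) != length(obs)) stop("ipred and obs differ in length")
  err <- ipred - obs
  nz <- obs != 0
  list(MPE = mean(err), MAE = mean(abs(err)),
       MPE_pct = 100 * mean(err[nz] / obs[nz]),
       MAE_pct = 100 * mean(abs(err[nz] / obs[nz])),
       RMSE = sqrt(mean(err^2)),
       n = length(obs), n_excluded_relative = sum(!nz))
}

#' Prediction-error metrics on an external dataset
#'
#' Bayesian forecasting: with the population parameters fixed, each external
#' subject's random effects are set to their conditional modes given all of
#' the subject's observations, and the individual predictions are compared
#' with the observations by the five standard metrics: mean prediction error
#' (MPE, mg/L), mean relative prediction error (MPE%, %), mean absolute
#' prediction error (MAE, mg/L), mean relative absolute prediction error
#' (MAE%, %), and root mean squared prediction error (RMSE, mg/L).
#' Observations equal to 0 are excluded from the relative metrics with a
#' count.
#'
#' @param model a [pk_model()] at its population estimates (e.g. `fit$model`).
#' @param data external event-table dataset carrying the covariates the model
#'   needs.
#' @return An object of class `"pk_validation"`: the five metrics, `n`, the
#'   per-observation errors (for paired comparisons), and the number of
#'   observations excluded from relative metrics.
#' @export
external_validation <- function(model, data) {
  design <- pk_design(data)
  eb <- map_eta(data, model)
  eta <- as.matrix(eb[, grep("^eta_", names(eb)), drop = FALSE])
  typ <- typical_parameters(model, design$cov)
  ip <- ind_params(typ, eta, names(model$omega[model$omega > 0]))
  ipred <- design_pred(design, ip$cl, ip$v)
  m <- prediction_metrics(ipred, design$y)
  err <- ipred - design$y
  structure(c(m, list(errors = err, abs_errors = abs(err),
                      ID = design$ids[design$obs_sid],
                      time = design$obs_time)),
            class = "pk_validation")
}

#' @export
print.pk_validation <- function(x, ...) {
  cat("External validation (n = ", x$n, ")\n", sep = "")
  cat(sprintf("  MPE  %8.4f mg/L    MPE%%  %7.3f %%\n", x$MPE, x$MPE_pct))
  cat(sprintf("  MAE  %8.4f mg/L    MAE%%  %7.3f %%\n", x$MAE, x$MAE_pct))
  cat(sprintf("  RMSE %8.4f mg/L\n", x$RMSE))
  if (x$n_excluded_relative > 0)
    cat("  (", x$n_excluded_relative,
        "zero observations excluded from relative metrics )\n")
  invisible(x)
}

#' Paired comparison of two models' external predictions
#'
#' Two-sided Wilcoxon signed-rank test on the paired absolute individual
#' prediction errors of two models evaluated on the same observations;
#' `p > 0.05` is reported as no statistical difference. All-zero differences
#' are a degenerate case reported as identical predictions.
#'
#' @param a,b [external_validation()] results on the same dataset.
#' @return list with `statistic`, `p_value`, `different` (logical at the 5%
#'   level), `degenerate`.
#' @export
compare_models_paired <- function(a, b) {
  if (a$n != b$n) stop("validation reports cover different observation sets")
  d <- a$abs_errors - b$abs_errors
  if (all(d == 0)) {
    return(list(statistic = NA_real_, p_value = 1, different = FALSE,
                degenerate = TRUE))
  }
  wt <- suppressWarnings(stats::wilcox.test(a$abs_errors, b$abs_errors,
                                            paired = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       different = wt$p.value <= 0.05, degenerate = FALSE)
}
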