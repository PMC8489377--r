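#' @export
coef.pkfit <- function(object, ...) {
  om <- object$omega
  names(om) <- paste0("omega_", names(om))
  sg <- c(sigma = object$error$sigma)
  if (object$error$form == "mixed") sg <- c(sg, sigma2 = object$error$sigma2)
  c(object$theta, om, sg)
}

#' @export
print.pkfit <- function(x, ...) {
  cat("Population PK fit (FOCE-I), model:", x$model$name, "\n")
  cat("  subjects:", x$design$n, "  observations:", x$design$nobs, "\n")
  cat("  OFV:", round(x$ofv, 3), "\n")
  cat("  convergence:",
      if (x$convergence == 0) "ok" else paste0("code ", x$convergence),
      paste0("(", x$message, ", ", x$iterations, " iterations)"), "\n")
  cat("  estimates:\n")
  print(round(coef(x), 4))
  invisible(x)
}

#' @export
fitted.pkfit <- function(object, type = c("individual", "population"), ...) {
  type <- match.arg(type)
  fitted_conc(object, individual = type == "individual")
}

#' Approximate covariance of the estimates
#'
#' Finite-difference Hessian of the OFV at the optimum on the natural scale;
#' the covariance is twice its inverse (the OFV is -2 log-likelihood).
#' Intended for relative standard errors, not for model selection.
#'
#' @param object a [pkfit()].
#' @param h relative finite-difference step.
#' @param ... unused.
#' @return covariance matrix over `coef(object)`.
#' @export
vcov.pkfit <- function(object, h = 1e-3, ...) {
  est <- coef(object)
  p <- length(est)
  model <- object$model
  design <- object$design
  ofv_at <- function(par) {
    m <- model
    k <- length(m$theta)
    m$theta[] <- par[seq_len(k)]
    no <- length(m$omega)
    m$omega[] <- par[k + seq_len(no)]
    m$error$sigma <- par[k + no + 1L]
    if (m$error$form == "mixed") m$error$sigma2 <- par[k + no + 2L]
    v <- ofv_core(design, m, inner_tol = 1e-9)
    if (!is.finite(v)) 1e10 else v
  }
  hs <- pmax(abs(est), 0.05) * h
  H <- matrix(NA_real_, p, p)
  f0 <- ofv_at(est)
  fp <- fm <- numeric(p)
  for (j in seq_len(p)) {
    ej <- numeric(p); ej[j] <- hs[j]
    fp[j] <- ofv_at(est + ej); fm[j] <- ofv_at(est - ej)
    H[j, j] <- (fp[j] - 2 * f0 + fm[j]) / hs[j]^2
  }
  for (j in seq_len(p)) for (l in seq_len(p)) if (l > j) {
    ej <- numeric(p); ej[j] <- hs[j]
    el <- numeric(p); el[l] <- hs[l]
    fpp <- ofv_at(est + ej + el)
    H[j, l] <- H[l, j] <- (fpp - fp[j] - fp[l] + f0) / (hs[j] * hs[l])
  }
  cv <- tryCatch(2 * solve(H), error = function(e) {
    warning("OFV Hessian numerically singular; covariance unavailable")
    matrix(NA_real_, p, p)
  })
  dimnames(cv) <- list(names(est), names(est))
  cv
}

#' @export
summary.pkfit <- function(object, se = FALSE, ...) {
  est <- coef(object)
  tab <- data.frame(parameter = names(est), estimate = unname(est))
  if (se) {
    cv <- vcov(object)
    tab$se <- sqrt(pmax(diag(cv), 0))
    tab$rse_pct <- 100 * tab$se / abs(tab$estimate)
  }
  out <- list(table = tab, ofv = object$ofv, shrinkage = object$shrinkage,
              n = object$design$n, nobs = object$design$nobs,
              convergence = object$convergence, model = object$model$name)
  class(out) <- "summary.pkfit"
  out
}

#' @export
print.summary.pkfit <- function(x, ...) {
  cat("Population PK model:", x$model, "\n")
  cat("subjects:", x$n, " observations:", x$nobs, " OFV:", round(x$ofv, 3), "\n\n")
  print(x$table, row.names = FALSE, digits = 4)
  cat("\nshrinkage (%):\n")
  print(round(x$shrinkage, 1))
  invisible(x)
}

#' Predictions for new subjects
#'
#' `type = "population"` evaluates the typical-value model (random effects at
#' zero) at the observation rows of `newdata`; `type = "individual"` first
#' estimates each new subject's random effects from that subject's own
#' observations with the population parameters fixed (Bayesian forecasting),
#' then predicts.
#'
#' @param object a [pkfit()].
#' @param newdata event-table dataset; defaults to the fitted data.
#' @param type `"individual"` or `"population"`.
#' @param ... unused.
#' @return numeric vector of predicted concentrations (mg/L), one per
#'   observation row.
#' @export
predict.pkfit <- function(object, newdata = NULL,
                          type = c("individual", "population"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) return(fitted(object, type = type))
  design <- pk_design(newdata)
  typ <- typical_parameters(object$model, design$cov)
  if (type == "population") return(design_pred(design, typ$CL, typ$V))
  eb <- map_eta(newdata, object$model)
  eta <- as.matrix(eb[, grep("^eta_", names(eb)), drop = FALSE])
  ip <- ind_params(typ, eta, names(object$omega[object$omega > 0]))
  design_pred(design, ip$cl, ip$v)
}

#' @export
residuals.pkfit <- function(object, type = c("cwres", "iwres", "response"), ...) {
  type <- match.arg(type)
  g <- gof_residuals(object)
  switch(type, cwres = g$CWRES, iwres = g$IWRES, response = g$DV - g$PRED)
}

#' Simulate replicate observation vectors from a fit
#'
#' Draws `nsim` replicates of the observation vector under the fitted design:
#' new random effects and residual errors at the original subjects, doses and
#' sampling times.
#'
#' @param object a [pkfit()].
#' @param nsim number of replicates.
#' @param seed seed.
#' @param ... unused.
#' @return data.frame with one column per replicate (`sim_1`, ...), rows in
#'   the order of the observation rows of the fitted data.
#' @export
simulate.pkfit <- function(object, nsim = 1, seed = 1L, ...) {
  out <- as.data.frame(with_seed(seed,
    simulate_dv(object$design, object$model, nsim)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Goodness-of-fit panels
#'
#' Classic four-panel display: DV vs PRED, DV vs IPRED (unity line), CWRES vs
#' PRED and CWRES vs time (zero line, +/-2 band).
#'
#' @param x a [pkfit()].
#' @param ... graphics arguments passed on.
#' @export
plot.pkfit <- function(x, ...) {
  g <- gof_residuals(x)
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  lim <- range(g$DV, g$PRED, g$IPRED)
  graphics::plot(g$PRED, g$DV, xlim = lim, ylim = lim, pch = 19, cex = 0.6,
                 xlab = "PRED (mg/L)", ylab = "DV (mg/L)", main = "DV vs PRED", ...)
  graphics::abline(0, 1, col = "grey50")
  graphics::plot(g$IPRED, g$DV, xlim = lim, ylim = lim, pch = 19, cex = 0.6,
                 xlab = "IPRED (mg/L)", ylab = "DV (mg/L)", main = "DV vs IPRED", ...)
  graphics::abline(0, 1, col = "grey50")
  graphics::plot(g$PRED, g$CWRES, pch = 19, cex = 0.6,
                 xlab = "PRED (mg/L)", ylab = "CWRES", main = "CWRES vs PRED", ...)
  graphics::abline(h = c(-2, 0, 2), lty = c(2, 1, 2), col = "grey50")
  graphics::plot(g$time, g$CWRES, pch = 19, cex = 0.6,
                 xlab = "time (h)", ylab = "CWRES", main = "CWRES vs time", ...)
  graphics::abline(h = c(-2, 0, 2), lty = c(2, 1, 2), col = "grey50")
  invisible(x)
}

#' Serialize a fit report to JSON
#'
#' Writes estimates, OFV, shrinkage and convergence status; the empirical
#' Bayes estimates go to a companion CSV when `ebe_path` is given.
#'
#' @param fit a [pkfit()].
#' @param path JSON output path.
#' @param ebe_path optional CSV path for the per-subject EBE table.
#' @export
write_fit_report <- function(fit, path, ebe_path = NULL) {
  jsonlite::write_json(list(
    model = fit$model$name,
    estimates = as.list(coef(fit)),
    ofv = fit$ofv,
    shrinkage_pct = as.list(fit$shrinkage),
    convergence = fit$convergence, message = fit$message,
    iterations = fit$iterations,
    n_subjects = fit$design$n, n_observations = fit$design$nobs),
    path, auto_unbox = TRUE, digits = NA)
  if (!is.null(ebe_path)) {
    ebe <- data.frame(ID = fit$design$ids)
    for (j in seq_len(ncol(fit$eta)))
      ebe[[paste0("eta_", colnames(fit$eta)[j])]] <- fit$eta[, j]
    utils::write.csv(ebe, ebe_path, row.names = FALSE)
  }
  invisible(path)
}
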