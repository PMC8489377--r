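## ---------------------------------------------------------------------------
## Internal dataset design: flattened observation/dose structure that lets the
## whole cohort's predictions and conditional likelihoods be computed with a
## handful of vectorised operations (no per-subject loops in the hot path).
## ---------------------------------------------------------------------------

cov_columns <- c("WT", "HT", "SCR", "AGE", "PRETERM", "SEX", "ALT", "AST",
                 "BUN", "CYSC", "ALB", "TP", "COMED", "EGFR")

pk_design <- function(data) {
  data <- validate_pkdata(data)
  ids <- unique(data$ID)
  n <- length(ids)
  sid_all <- match(data$ID, ids)
  is_obs <- data$EVID == 0
  is_dose <- data$EVID == 1
  obs_sid <- sid_all[is_obs]
  obs_time <- data$TIME[is_obs]
  y <- data$DV[is_obs]
  kind <- if (!is.null(data$KIND)) as.character(data$KIND[is_obs]) else
    rep(NA_character_, sum(is_obs))
  dose_sid <- sid_all[is_dose]
  dose_start <- data$TIME[is_dose]
  dose_amt <- data$AMT[is_dose]
  dose_dur <- data$DUR[is_dose]
  cov <- data[match(ids, data$ID), intersect(cov_columns, names(data)),
              drop = FALSE]
  rownames(cov) <- NULL
  dose_by_sid <- split(seq_along(dose_start), factor(dose_sid, levels = seq_len(n)))
  ndose <- lengths(dose_by_sid)
  pair_dose <- unlist(dose_by_sid[obs_sid], use.names = FALSE)
  pair_obs <- rep(seq_along(obs_sid), ndose[obs_sid])
  list(ids = ids, n = n, nobs = length(y), cov = cov,
       obs_sid = obs_sid, obs_time = obs_time, y = y, kind = kind,
       dose_sid = dose_sid, dose_start = dose_start, dose_amt = dose_amt,
       dose_dur = dose_dur,
       pair_obs = pair_obs, pair_sid = obs_sid[pair_obs],
       pair_dt = obs_time[pair_obs] - dose_start[pair_dose],
       pair_amt = dose_amt[pair_dose], pair_dur = dose_dur[pair_dose],
       data = data)
}

# Predicted concentration at every observation row for per-subject CL/V.
design_pred <- function(design, cl, v) {
  cc <- conc_pairs(design$pair_dt, design$pair_amt, design$pair_dur,
                   cl[design$pair_sid], v[design$pair_sid])
  as.vector(rowsum(cc, design$pair_obs, reorder = FALSE))
}

# Per-subject conditional -2 log-likelihood of the observations given
# predictions f (Gaussian, variance from the residual-error form).
subj_cond_m2ll <- function(design, f, error) {
  vv <- residual_variance(f, error)
  ll <- log(2 * pi * vv) + (design$y - f)^2 / vv
  ll[!is.finite(ll)] <- 1e10
  as.vector(rowsum(ll, design$obs_sid, reorder = FALSE))
}

# eta matrix (n x d) -> per-subject CL/V including BSV. `edim` names the
# random-effect dimensions ("CL", "V").
ind_params <- function(typ, eta, edim) {
  cl <- typ$CL
  v <- typ$V
  j <- match("CL", edim)
  if (!is.na(j)) cl <- cl * exp(eta[, j])
  j <- match("V", edim)
  if (!is.na(j)) v <- v * exp(eta[, j])
  list(cl = cl, v = v)
}

## ---------------------------------------------------------------------------
## Inner step: per-subject conditional modes (empirical Bayes estimates), all
## subjects advanced simultaneously by a damped Newton iteration with
## finite-difference derivatives.
## ---------------------------------------------------------------------------

inner_newton <- function(design, typ, error, omega_sd,
                         tol = 1e-7, max_iter = 50L, h = 1e-4,
                         eta_start = NULL) {
  edim <- names(omega_sd)
  d <- length(edim)
  n <- design$n
  om2 <- omega_sd^2
  prior_const <- sum(log(2 * pi * om2))
  qfun <- function(eta) {
    ip <- ind_params(typ, eta, edim)
    q <- subj_cond_m2ll(design, design_pred(design, ip$cl, ip$v), error)
    q + as.vector(eta^2 %*% (1 / om2)) + prior_const
  }
  eta <- if (is.null(eta_start)) matrix(0, n, d) else eta_start
  q0 <- qfun(eta)
  g <- matrix(0, n, d)
  H <- array(0, c(n, d, d))
  conv <- FALSE
  for (iter in seq_len(max_iter)) {
    for (j in seq_len(d)) {
      ej <- matrix(0, n, d); ej[, j] <- h
      qp <- qfun(eta + ej); qm <- qfun(eta - ej)
      g[, j] <- (qp - qm) / (2 * h)
      H[, j, j] <- (qp - 2 * q0 + qm) / h^2
    }
    if (d == 2L) {
      e12 <- matrix(h, n, 2L)
      qpp <- qfun(eta + e12)
      ej1 <- matrix(0, n, 2L); ej1[, 1L] <- h
      ej2 <- matrix(0, n, 2L); ej2[, 2L] <- h
      H12 <- (qpp - qfun(eta + ej1) - qfun(eta + ej2) + q0) / h^2
      H[, 1L, 2L] <- H[, 2L, 1L] <- H12
    }
    # guard against non-finite derivatives at extreme trial parameters
    g[!is.finite(g)] <- 0
    H[!is.finite(H)] <- 2 / max(om2)
    if (max(abs(g)) < tol * (1 + max(abs(q0)))) { conv <- TRUE; break }
    step <- matrix(0, n, d)
    if (d == 1L) {
      step[, 1L] <- -g[, 1L] / pmax(H[, 1L, 1L], 2 / max(om2))
    } else {
      for (i in seq_len(n)) {
        Hi <- H[i, , ]
        ridge <- 0
        while (TRUE) {
          ev <- tryCatch(min(eigen(Hi + diag(ridge, d), TRUE, TRUE)$values),
                         error = function(e) -1)
          if (ev > 1e-8) break
          ridge <- max(ridge * 10, 1e-4)
        }
        step[i, ] <- -solve(Hi + diag(ridge, d), g[i, ])
      }
    }
    sn <- sqrt(rowSums(step^2))
    too_big <- sn > 3
    if (any(too_big)) step[too_big, ] <- step[too_big, , drop = FALSE] * (3 / sn[too_big])
    # vectorised backtracking
    lam <- rep(1, n)
    for (bt in 1:12) {
      qn <- qfun(eta + step * lam)
      bad <- qn > q0 + 1e-10
      if (!any(bad)) break
      lam[bad] <- lam[bad] / 2
    }
    stalled <- qn > q0 + 1e-10
    move <- eta + step * lam
    move[stalled, ] <- eta[stalled, , drop = FALSE]
    qn[stalled] <- q0[stalled]
    if (max(abs(qn - q0)) < 1e-12 && iter > 3L) { eta <- move; q0 <- qn; conv <- TRUE; break }
    eta <- move
    q0 <- qn
  }
  # final curvature (log-determinant needed by the Laplace objective)
  for (j in seq_len(d)) {
    ej <- matrix(0, n, d); ej[, j] <- h
    qp <- qfun(eta + ej); qm <- qfun(eta - ej)
    g[, j] <- (qp - qm) / (2 * h)
    H[, j, j] <- (qp - 2 * q0 + qm) / h^2
  }
  if (d == 2L) {
    e12 <- matrix(h, n, 2L)
    ej1 <- matrix(0, n, 2L); ej1[, 1L] <- h
    ej2 <- matrix(0, n, 2L); ej2[, 2L] <- h
    H12 <- (qfun(eta + e12) - qfun(eta + ej1) - qfun(eta + ej2) + q0) / h^2
    H[, 1L, 2L] <- H[, 2L, 1L] <- H12
  }
  H[!is.finite(H)] <- 2 / max(om2)
  floor_h <- 1 / max(om2)
  logdet <- if (d == 1L) {
    log(pmax(H[, 1L, 1L], floor_h))
  } else {
    dt <- H[, 1L, 1L] * H[, 2L, 2L] - H[, 1L, 2L]^2
    log(pmax(dt, floor_h^2))
  }
  list(eta = eta, q = q0, H = H, logdet = logdet, converged = conv)
}

## ---------------------------------------------------------------------------
## FOCE-I / Laplace marginal -2 log-likelihood
## ---------------------------------------------------------------------------

# Core objective on a prepared design. Returns the scalar OFV; the full inner
# solution is attached as an attribute when detail = TRUE.
ofv_core <- function(design, model, theta = model$theta,
                     omega_sd = model$omega, error = model$error,
                     eta_start = NULL, inner_tol = 1e-7, detail = FALSE) {
  typ <- tryCatch(typical_parameters(model, design$cov, theta),
                  error = function(e) NULL)
  if (is.null(typ)) return(NA_real_)
  omega_sd <- omega_sd[omega_sd > 0]
  if (length(omega_sd) == 0L) {
    f <- design_pred(design, typ$CL, typ$V)
    ofv <- sum(subj_cond_m2ll(design, f, error))
    if (detail) attr(ofv, "inner") <-
        list(eta = matrix(0, design$n, 0), q = NULL, logdet = NULL,
             converged = TRUE)
    return(ofv)
  }
  inn <- inner_newton(design, typ, error, omega_sd, tol = inner_tol,
                      eta_start = eta_start)
  d <- length(omega_sd)
  ofv <- sum(inn$q) - design$n * d * log(4 * pi) + sum(inn$logdet)
  if (detail) attr(ofv, "inner") <- inn
  ofv
}

#' FOCE objective function value
#'
#' Computes the first-order-conditional (with interaction) approximation to
#' the \eqn{-2} log marginal likelihood of a population PK dataset under a
#' covariate model: each subject's random effect is set to its conditional
#' mode (empirical Bayes estimate) and the marginal integral is approximated
#' by the Laplace expansion about that mode, using the full conditional
#' curvature so the eta--epsilon interaction of the proportional error model
#' is retained. With all between-subject SDs zero the value reduces exactly to
#' the fixed-effects \eqn{-2} log-likelihood. All `log(2*pi)` constants are
#' included, so only OFV differences are comparable across implementations.
#'
#' @param data an event-table dataset (see [read_pkdata()]).
#' @param model a [pk_model()] carrying `theta`, `omega` and the error form.
#' @return The objective function value (dimensionless scalar).
#' @export
ofv_foce <- function(data, model) {
  ofv_core(pk_design(data), model)
}

#' Conditional -2 log-likelihood of each subject
#'
#' The Gaussian observation density given fixed random effects: for each
#' subject, \eqn{\sum_j [\log(2\pi v_j) + (y_j - f_j)^2/v_j]} with variance
#' \eqn{v_j} from the residual-error form (proportional: \eqn{\sigma^2 f_j^2}).
#' The random-effect prior is not included.
#'
#' @inheritParams ofv_foce
#' @param eta matrix (subjects x random effects, columns in the order of
#'   `model$omega`) or vector for a single random effect; defaults to 0.
#' @return Numeric vector, one value per subject (order of first appearance).
#' @export
individual_minus2ll <- function(data, model, eta = NULL) {
  design <- pk_design(data)
  edim <- names(model$omega)
  if (is.null(eta)) eta <- matrix(0, design$n, length(edim))
  eta <- matrix(eta, nrow = design$n)
  typ <- typical_parameters(model, design$cov)
  ip <- ind_params(typ, eta, edim)
  out <- subj_cond_m2ll(design, design_pred(design, ip$cl, ip$v), model$error)
  names(out) <- design$ids
  out
}

#' Empirical Bayes estimates (conditional modes) of the random effects
#'
#' Minimises, per subject, the conditional \eqn{-2} log-likelihood plus the
#' log-normal prior penalty \eqn{\eta^\top \Omega^{-1} \eta + \log|2\pi\Omega|},
#' returning the mode and the curvature (Hessian of the joint \eqn{-2}
#' log-density) at the mode. Deterministic given data and parameters.
#'
#' @inheritParams ofv_foce
#' @return data.frame with subject `ID`, one `eta_*` column per random effect,
#'   and `curvature` (for one random effect) or the determinant of the
#'   curvature matrix (for two).
#' @export
map_eta <- function(data, model) {
  design <- pk_design(data)
  omega_sd <- model$omega[model$omega > 0]
  if (length(omega_sd) == 0L) stop("map_eta requires omega > 0")
  typ <- typical_parameters(model, design$cov)
  inn <- inner_newton(design, typ, model$error, omega_sd)
  out <- data.frame(ID = design$ids)
  for (j in seq_along(omega_sd))
    out[[paste0("eta_", names(omega_sd)[j])]] <- inn$eta[, j]
  out$curvature <- exp(inn$logdet)
  attr(out, "converged") <- inn$converged
  out
}

#' Adaptive Gauss--Hermite reference for the marginal likelihood
#'
#' Computes the \eqn{-2} log marginal likelihood of each subject by adaptive
#' Gauss--Hermite quadrature (nodes centred at the conditional mode and scaled
#' by its curvature), summed over subjects. Only models with a single random
#' effect are supported. Serves as the accuracy reference for [ofv_foce()].
#'
#' @inheritParams ofv_foce
#' @param n_nodes number of quadrature nodes (default 64, minimum 8).
#' @return The quadrature \eqn{-2} log marginal likelihood.
#' @export
ofv_quadrature_oracle <- function(data, model, n_nodes = 64L) {
  omega_sd <- model$omega[model$omega > 0]
  if (length(omega_sd) == 0L) return(ofv_foce(data, model))
  if (length(omega_sd) != 1L)
    stop("quadrature reference supports a single random effect")
  if (n_nodes < 8L) stop("n_nodes must be >= 8")
  design <- pk_design(data)
  typ <- typical_parameters(model, design$cov)
  inn <- inner_newton(design, typ, model$error, omega_sd, tol = 1e-9)
  gh <- pracma::gaussHermite(n_nodes)
  om2 <- omega_sd^2
  scale_i <- sqrt(2 / pmax(inn$H[, 1L, 1L], 1e-8))   # Laplace SD per subject
  edim <- names(omega_sd)
  # per-subject joint -2 log density at arbitrary eta vector
  qfun <- function(eta) {
    ip <- ind_params(typ, matrix(eta, ncol = 1L), edim)
    subj_cond_m2ll(design, design_pred(design, ip$cl, ip$v), model$error) +
      eta^2 / om2 + log(2 * pi * om2)
  }
  logint <- matrix(NA_real_, design$n, n_nodes)
  for (k in seq_len(n_nodes)) {
    etak <- inn$eta[, 1L] + sqrt(2) * scale_i * gh$x[k]
    logint[, k] <- log(gh$w[k]) + gh$x[k]^2 - qfun(etak) / 2
  }
  mx <- apply(logint, 1L, max)
  li <- mx + log(rowSums(exp(logint - mx))) + log(sqrt(2) * scale_i)
  if (any(!is.finite(li))) stop("quadrature produced a non-finite value")
  sum(-2 * li)
}

## ---------------------------------------------------------------------------
## Population fit
## ---------------------------------------------------------------------------

#' Control options for [pkfit()]
#'
#' @param iter.max,eval.max outer optimiser (nlminb) budgets.
#' @param rel.tol outer relative convergence tolerance on the OFV.
#' @param inner.tol gradient tolerance of the inner Newton step.
#' @param warm_start reuse the previous conditional modes as starting values
#'   across outer iterations. Off by default: the cold-started inner step is
#'   bitwise reproducible and keeps the outer finite-difference gradients
#'   clean; warm starting is faster but can degrade the optimiser's
#'   convergence diagnostics.
#' @return list of control values.
#' @export
pkfit_control <- function(iter.max = 400L, eval.max = 3000L, rel.tol = 1e-8,
                          inner.tol = 1e-8, warm_start = FALSE) {
  list(iter.max = iter.max, eval.max = eval.max, rel.tol = rel.tol,
       inner.tol = inner.tol, warm_start = warm_start)
}

# Parameter packing: theta (per model$par_info transforms), then log(omega),
# then log(sigma) (and log(sigma2) for the mixed form).
par_pack <- function(model) {
  info <- model$par_info
  th <- model$theta[info$name]
  p <- ifelse(info$transform == "log", log(th), th)
  names(p) <- info$name
  om <- log(model$omega)
  names(om) <- paste0("omega_", names(model$omega))
  sg <- log(model$error$sigma)
  names(sg) <- "sigma"
  if (model$error$form == "mixed") {
    sg <- c(sg, sigma2 = log(max(model$error$sigma2, 1e-6)))
  }
  c(p, om, sg)
}

par_unpack <- function(p, model) {
  info <- model$par_info
  k <- nrow(info)
  th <- p[seq_len(k)]
  th <- ifelse(info$transform == "log", exp(th), th)
  names(th) <- info$name
  no <- length(model$omega)
  om <- exp(p[k + seq_len(no)])
  names(om) <- names(model$omega)
  sg <- unname(exp(p[k + no + 1L]))
  err <- residual_error(model$error$form, sg,
                        if (model$error$form == "mixed")
                          unname(exp(p[k + no + 2L])) else 0)
  list(theta = th, omega = om, error = err)
}

#' Fit a population PK model by FOCE
#'
#' Maximum (approximate) marginal likelihood estimation of the fixed effects,
#' between-subject variance and residual variance of a one-compartment
#' infusion model with log-normal between-subject variability:
#' minimises [ofv_foce()] over \eqn{(\theta, \omega, \sigma)} with variance
#' components log-transformed (positivity enforced) by a quasi-Newton outer
#' optimiser (nlminb). Estimation is deterministic given data, starting
#' values and control settings. Non-convergence is never silent: the returned
#' object carries the optimiser status and the best point found.
#'
#' @param data an event-table dataset (see [read_pkdata()]); every subject
#'   needs at least one dose and one observation row. A warning is issued when
#'   subjects have a single observation (weakly identified random effects).
#' @param model a [pk_model()]; its `theta`, `omega` and error SD serve as the
#'   default starting values.
#' @param init optional named list/vector overriding starting values; entries
#'   among the theta names, `omega_CL`, `omega_V`, `sigma`, `sigma2`.
#' @param control a [pkfit_control()] list.
#' @return An object of class `"pkfit"` with components `model` (the model at
#'   the estimates), `theta`, `omega`, `error`, `ofv`, `eta` (empirical Bayes
#'   estimates), `shrinkage`, `convergence`, `iterations`, `design` and `data`.
#' @examples
#' \donttest{
#' cfg <- cohort_config(n = 24, group = "augmented", seed = 7)
#' dat <- simulate_cohort(cfg, vanco_model("model2"))
#' fit <- pkfit(dat, vanco_model("model2"))
#' coef(fit)
#' }
#' @export
pkfit <- function(data, model, init = NULL, control = pkfit_control()) {
  design <- pk_design(data)
  nobs_per <- tabulate(design$obs_sid, design$n)
  if (any(nobs_per < 2L))
    warning(sum(nobs_per < 2L),
            " subject(s) have a single observation; random effects weakly identified")
  start_model <- model
  if (!is.null(init)) {
    init <- unlist(init)
    for (nm in names(init)) {
      if (nm %in% names(start_model$theta)) start_model$theta[nm] <- init[nm]
      else if (nm == "sigma") start_model$error$sigma <- init[nm]
      else if (nm == "sigma2") start_model$error$sigma2 <- init[nm]
      else if (nm %in% paste0("omega_", names(start_model$omega)))
        start_model$omega[sub("^omega_", "", nm)] <- init[nm]
      else stop("unknown init parameter '", nm, "'")
    }
  }
  p0 <- par_pack(start_model)
  env <- new.env(parent = emptyenv())
  env$eta <- NULL
  objective <- function(p) {
    pp <- par_unpack(p, start_model)
    ofv <- ofv_core(design, start_model, theta = pp$theta,
                    omega_sd = pp$omega, error = pp$error,
                    eta_start = if (control$warm_start) env$eta else NULL,
                    inner_tol = control$inner.tol, detail = control$warm_start)
    if (control$warm_start && !is.null(attr(ofv, "inner")))
      env$eta <- attr(ofv, "inner")$eta
    v <- as.numeric(ofv)
    if (!is.finite(v)) 1e10 else v
  }
  opt <- nlminb(p0, objective,
                control = list(iter.max = control$iter.max,
                               eval.max = control$eval.max,
                               rel.tol = control$rel.tol))
  # cheap restarts from the found point clean up marginal convergence codes
  for (r in 1:2) {
    if (opt$convergence == 0) break
    opt2 <- nlminb(opt$par, objective,
                   control = list(iter.max = control$iter.max,
                                  eval.max = control$eval.max,
                                  rel.tol = control$rel.tol))
    if (opt2$objective <= opt$objective) opt <- opt2 else break
  }
  pp <- par_unpack(opt$par, start_model)
  final <- start_model
  final$theta <- pp$theta
  final$omega <- pp$omega
  final$error <- pp$error
  ofv <- ofv_core(design, final, inner_tol = 1e-9, detail = TRUE)
  inn <- attr(ofv, "inner")
  omega_pos <- final$omega[final$omega > 0]
  eta <- inn$eta
  colnames(eta) <- names(omega_pos)
  fit <- structure(list(
    model = final, theta = pp$theta, omega = pp$omega, error = pp$error,
    ofv = as.numeric(ofv), eta = eta,
    convergence = opt$convergence, message = opt$message,
    iterations = opt$iterations, design = design, data = design$data,
    init = p0, call = match.call()), class = "pkfit")
  fit$shrinkage <- compute_shrinkage(fit)
  fit
}

#' Evaluate a model on a dataset without re-estimating
#'
#' Builds a `"pkfit"` object at the model's current parameters: conditional
#' modes, OFV and shrinkage are computed, but no population parameters are
#' estimated. Useful for diagnostics (GOF, VPC, shrinkage) of a published
#' model on new data.
#'
#' @inheritParams pkfit
#' @return A `"pkfit"` object with `convergence = 0` and 0 iterations.
#' @export
pkfit_at <- function(data, model) {
  design <- pk_design(data)
  ofv <- ofv_core(design, model, inner_tol = 1e-9, detail = TRUE)
  inn <- attr(ofv, "inner")
  omega_pos <- model$omega[model$omega > 0]
  eta <- inn$eta
  colnames(eta) <- names(omega_pos)
  fit <- structure(list(
    model = model, theta = model$theta, omega = model$omega,
    error = model$error, ofv = as.numeric(ofv), eta = eta,
    convergence = 0L, message = "evaluation only", iterations = 0L,
    design = design, data = design$data, init = par_pack(model),
    call = match.call()), class = "pkfit")
  fit$shrinkage <- compute_shrinkage(fit)
  fit
}

#' Shrinkage of the empirical Bayes estimates
#'
#' Eta-shrinkage per random effect, \eqn{100 (1 - SD(\hat\eta)/\omega)}, and
#' epsilon-shrinkage \eqn{100 (1 - SD(IWRES))} with
#' \eqn{IWRES = (y - IPRED)/\sqrt{v(IPRED)}} (proportional form:
#' \eqn{v = \sigma^2 IPRED^2}). Low shrinkage indicates the individual data
#' are informative enough for EBE-based diagnostics.
#'
#' @param fit a [pkfit()] result.
#' @return named numeric vector: `eta_CL` (and `eta_V` when present) and
#'   `epsilon`, in percent. `NA` for random effects with `omega = 0`.
#' @export
compute_shrinkage <- function(fit) {
  omega_pos <- fit$omega[fit$omega > 0]
  out <- numeric(0)
  for (j in seq_along(omega_pos)) {
    out[paste0("eta_", names(omega_pos)[j])] <-
      100 * (1 - stats::sd(fit$eta[, j]) / omega_pos[j])
  }
  ipred <- fitted_conc(fit, individual = TRUE)
  iwres <- (fit$design$y - ipred) / sqrt(residual_variance(ipred, fit$error))
  out["epsilon"] <- 100 * (1 - stats::sd(iwres))
  out
}

# Predicted concentrations at the observation rows: population (eta = 0) or
# individual (eta at the EBEs).
fitted_conc <- function(fit, individual = TRUE) {
  typ <- typical_parameters(fit$model, fit$design$cov)
  if (!individual || ncol(fit$eta) == 0L)
    return(design_pred(fit$design, typ$CL, typ$V))
  ip <- ind_params(typ, fit$eta, colnames(fit$eta))
  design_pred(fit$design, ip$cl, ip$v)
}
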