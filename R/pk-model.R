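#' Residual-error specification
#'
#' The three classical residual models for an observation with individual
#' prediction F: additive `Y = F + e`, proportional `Y = F (1 + e)`, and mixed
#' `Y = F (1 + e1) + e2`. Standard deviations, not variances, are stored.
#'
#' @param form `"additive"`, `"proportional"`, or `"mixed"`.
#' @param sigma SD of the (first) error component; proportional SDs are
#'   dimensionless fractions, additive SDs are mg/L.
#' @param sigma2 additive SD of the second component (mixed form only).
#' @return An object of class `"residual_error"`.
#' @export
residual_error <- function(form = c("proportional", "additive", "mixed"),
                           sigma, sigma2 = 0) {
  form <- match.arg(form)
  if (!is.finite(sigma) || sigma < 0) stop("sigma must be >= 0")
  if (!is.finite(sigma2) || sigma2 < 0) stop("sigma2 must be >= 0")
  if (form != "mixed" && sigma2 != 0)
    stop("sigma2 is only used by the mixed error form")
  structure(list(form = form, sigma = sigma, sigma2 = sigma2),
            class = "residual_error")
}

# Residual variance of Y given prediction f (vectorised).
residual_variance <- function(f, error) {
  switch(error$form,
         additive     = rep_len(error$sigma^2, length(f)),
         proportional = error$sigma^2 * f^2,
         mixed        = error$sigma^2 * f^2 + error$sigma2^2)
}

#' Apply a residual-error draw to predictions
#'
#' @param f predicted concentrations (mg/L), `>= 0`.
#' @param error a [residual_error()] specification.
#' @param eps draw of the first error component (same length as `f`); for the
#'   proportional and mixed forms this is the fractional component.
#' @param eps2 draw of the second (additive) component, mixed form only.
#' @return Simulated observations Y (mg/L); negative values are possible under
#'   the statistical model and are left untouched.
#' @export
apply_residual <- function(f, error, eps, eps2 = 0) {
  if (any(f < 0)) stop("predictions must be >= 0")
  switch(error$form,
         additive     = f + eps,
         proportional = f * (1 + eps),
         mixed        = f * (1 + eps) + eps2)
}

#' Apply between-subject variability to typical parameters
#'
#' Log-normal between-subject variability: each parameter is multiplied by
#' `exp(eta)`; `eta = 0` returns the typical values.
#'
#' @param typical data.frame or list with elements `CL` and `V` (typical values).
#' @param eta_cl,eta_v random effects on CL and V (recycled; default 0).
#' @return list with `CL` and `V`.
#' @export
apply_bsv <- function(typical, eta_cl = 0, eta_v = 0) {
  if (any(!is.finite(eta_cl)) || any(!is.finite(eta_v)))
    stop("eta must be finite")
  list(CL = typical$CL * exp(eta_cl), V = typical$V * exp(eta_v))
}

## ---------------------------------------------------------------------------
## Covariate model specification
##
## A pk_model is a pair of multiplicative term lists for CL and V plus the
## intercepts TVCL/TVV. Term types:
##   power           (COV/median)^theta            1 estimated exponent
##   power_fixed     (COV/median)^exponent         fixed exponent
##   linear_ratio    COV/median                    no parameter
##   expslope        exp(theta * COV/median)       1 estimated slope
##   sigmoid_mf      Age^Hill / (TM50^Hill + Age^Hill)   TM50, Hill estimated
##   sigmoid_exp     (WT/median)^m,  m = theta0 - kmax X^Hill/(k50^Hill+X^Hill)
##                   with X the scaling covariate; theta0, kmax, k50, Hill
## ---------------------------------------------------------------------------

pk_term <- function(type, cov, median = 1, pars = character(), fixed = list(),
                    xcov = NULL) {
  if (median <= 0) stop("centering median for ", cov, " must be > 0")
  structure(list(type = type, cov = cov, median = median, pars = pars,
                 fixed = fixed, xcov = xcov), class = "pk_term")
}

term_par_info <- function(term, prefix) {
  if (length(term$pars) == 0L) return(NULL)
  tr <- switch(term$type,
               power = "identity", expslope = "identity",
               sigmoid_mf = c("log", "log"),
               sigmoid_exp = c("identity", "log", "log", "log"))
  data.frame(name = paste0(prefix, "_", term$pars), transform = tr,
             stringsAsFactors = FALSE)
}

eval_term <- function(term, theta, prefix, cov_df) {
  need <- c(term$cov, term$xcov)
  for (nm in need) {
    if (is.null(cov_df[[nm]]))
      stop("covariate model requires covariate '", nm, "' which is missing")
  }
  x <- cov_df[[term$cov]]
  if (term$type %in% c("power", "power_fixed", "linear_ratio", "sigmoid_exp") &&
      any(x <= 0))
    stop("covariate '", term$cov, "' must be > 0 for this term")
  p <- function(suffix) theta[[paste0(prefix, "_", suffix)]]
  switch(term$type,
    power        = (x / term$median)^p(term$pars[1L]),
    power_fixed  = (x / term$median)^term$fixed$exponent,
    linear_ratio = x / term$median,
    expslope     = exp(p(term$pars[1L]) * x / term$median),
    sigmoid_mf   = {
      tm50 <- p("TM50"); hill <- p("HILL")
      x^hill / (tm50^hill + x^hill)
    },
    sigmoid_exp  = {
      xs <- cov_df[[term$xcov]]
      m <- p("THETA0") - p("KMAX") * xs^p("HILL") /
        (p("K50")^p("HILL") + xs^p("HILL"))
      (x / term$median)^m
    },
    stop("unknown term type '", term$type, "'"))
}

#' Construct a covariate model for CL and V
#'
#' Defines the structural typical-value model
#' \eqn{TVCL = \theta_1 \prod_j g_j(cov)} and
#' \eqn{TVV = \theta_2 \prod_j h_j(cov)} from multiplicative covariate terms,
#' together with between-subject variability (log-normal, on CL and optionally
#' V) and a residual-error form. The returned object drives simulation
#' ([simulate_cohort()]) and estimation ([pkfit()]).
#'
#' @param name model label.
#' @param cl_terms,v_terms lists of terms created by the internal term
#'   constructors; see [vanco_model()] and [maturation_model()] for the
#'   standard structures.
#' @param theta named numeric vector of parameter values: must contain `TVCL`,
#'   `TVV` and one entry per estimated term parameter.
#' @param omega named numeric vector of between-subject SDs; names among
#'   `"CL"`, `"V"`. Parameters listed here carry an `exp(eta)` random effect.
#' @param error a [residual_error()] specification.
#' @return An object of class `"pk_model"`.
#' @export
pk_model <- function(name, cl_terms = list(), v_terms = list(),
                     theta, omega = c(CL = 0.3),
                     error = residual_error("proportional", 0.3)) {
  info <- rbind(data.frame(name = c("TVCL", "TVV"), transform = "log",
                           stringsAsFactors = FALSE),
                do.call(rbind, c(
                  lapply(cl_terms, term_par_info, prefix = "CL"),
                  lapply(v_terms, term_par_info, prefix = "V"))))
  if (!all(info$name %in% names(theta)))
    stop("theta is missing parameters: ",
         paste(setdiff(info$name, names(theta)), collapse = ", "))
  theta <- theta[info$name]
  if (theta[["TVCL"]] <= 0 || theta[["TVV"]] <= 0)
    stop("TVCL and TVV must be > 0")
  if (!all(names(omega) %in% c("CL", "V"))) stop("omega names must be CL and/or V")
  if (any(omega < 0)) stop("omega must be >= 0")
  structure(list(name = name, cl_terms = cl_terms, v_terms = v_terms,
                 theta = theta, par_info = info, omega = omega, error = error),
            class = "pk_model")
}

#' @export
print.pk_model <- function(x, ...) {
  cat("Covariate PK model:", x$name, "\n")
  cat("  parameters:\n")
  print(round(x$theta, 4))
  cat("  BSV SD (omega):", paste(names(x$omega), round(x$omega, 3),
                                 sep = " = ", collapse = ", "), "\n")
  cat("  residual error:", x$error$form, "sigma =", x$error$sigma,
      if (x$error$form == "mixed") paste("sigma2 =", x$error$sigma2), "\n")
  invisible(x)
}

#' Typical individual parameters under a covariate model
#'
#' Evaluates the typical-value equations of a [pk_model()] for a set of
#' subjects.
#'
#' @param model a `pk_model`.
#' @param cov data.frame of covariates (one row per subject); columns as
#'   required by the model's terms (e.g. `WT`, `SCR`, `AGE`).
#' @param theta optional replacement parameter vector (defaults to the model's).
#' @return data.frame with columns `CL` (L/h) and `V` (L).
#' @examples
#' m2 <- vanco_model("model2")
#' typical_parameters(m2, data.frame(WT = 4.6))
#' @export
typical_parameters <- function(model, cov, theta = model$theta) {
  cov <- as.data.frame(cov)
  cl <- rep_len(theta[["TVCL"]], nrow(cov))
  for (tm in model$cl_terms) cl <- cl * eval_term(tm, theta, "CL", cov)
  v <- rep_len(theta[["TVV"]], nrow(cov))
  for (tm in model$v_terms) v <- v * eval_term(tm, theta, "V", cov)
  if (any(!is.finite(cl)) || any(cl <= 0) || any(!is.finite(v)) || any(v <= 0))
    stop("typical parameters must be finite and > 0; check theta and covariates")
  data.frame(CL = cl, V = v)
}

#' Published vancomycin infant models
#'
#' Registry of the three final renal-function-stratified covariate models with
#' their published estimates:
#' \describe{
#'   \item{model1}{normal renal function (eGFR 30--86):
#'     `CL = 0.407 (WT/2.25)^1.24 exp(-0.533 SCR/27.1)`,
#'     `V = 1.86 (WT/2.25)^1.28`; BSV-CL SD 0.315, proportional sigma 0.319.}
#'   \item{model2}{augmented renal clearance (eGFR >= 86):
#'     `CL = 0.756 (WT/4.6)^1.03`, `V = 4.89 (WT/4.6)^0.918`;
#'     BSV-CL SD 0.312, proportional sigma 0.319.}
#'   \item{model3}{whole population:
#'     `CL = 0.707 (WT/3.45)^1.23 exp(-0.377 SCR/19)`,
#'     `V = 3.39 (WT/3.45)^1.29`; BSV-CL SD 0.311, proportional sigma 0.335.}
#' }
#' WT in kg, SCR in \eqn{\mu}mol/L. Note the serum-creatinine factor is the
#' estimable form `exp(theta5 * SCR/median)`, which is not unity at the median.
#'
#' @param name `"model1"`, `"model2"`, or `"model3"`.
#' @return A [pk_model()] carrying the published estimates.
#' @export
vanco_model <- function(name = c("model1", "model2", "model3")) {
  name <- match.arg(name)
  switch(name,
    model1 = pk_model("model1",
      cl_terms = list(pk_term("power", "WT", 2.25, "WT"),
                      pk_term("expslope", "SCR", 27.1, "SCR")),
      v_terms  = list(pk_term("power", "WT", 2.25, "WT")),
      theta = c(TVCL = 0.407, TVV = 1.86, CL_WT = 1.24, V_WT = 1.28,
                CL_SCR = -0.533),
      omega = c(CL = 0.315),
      error = residual_error("proportional", 0.319)),
    model2 = pk_model("model2",
      cl_terms = list(pk_term("power", "WT", 4.6, "WT")),
      v_terms  = list(pk_term("power", "WT", 4.6, "WT")),
      theta = c(TVCL = 0.756, TVV = 4.89, CL_WT = 1.03, V_WT = 0.918),
      omega = c(CL = 0.312),
      error = residual_error("proportional", 0.319)),
    model3 = pk_model("model3",
      cl_terms = list(pk_term("power", "WT", 3.45, "WT"),
                      pk_term("expslope", "SCR", 19, "SCR")),
      v_terms  = list(pk_term("power", "WT", 3.45, "WT")),
      theta = c(TVCL = 0.707, TVV = 3.39, CL_WT = 1.23, V_WT = 1.29,
                CL_SCR = -0.377),
      omega = c(CL = 0.311),
      error = residual_error("proportional", 0.335)))
}

#' Published bootstrap percentile intervals
#'
#' 2.5--97.5% bootstrap percentile intervals reported for the registry models,
#' used as parameter-recovery acceptance bands in simulation studies.
#'
#' @param name registry model name.
#' @return data.frame with columns `parameter`, `lower`, `upper`.
#' @export
vanco_model_ci <- function(name = c("model1", "model2", "model3")) {
  name <- match.arg(name)
  switch(name,
    model1 = data.frame(
      parameter = c("TVCL", "TVV", "CL_WT", "V_WT", "CL_SCR", "omega_CL", "sigma"),
      lower = c(0.287, 1.58, 1.03, 0.818, -0.671, 0.159, 0.261),
      upper = c(0.483, 2.17, 1.43, 1.45, -0.199, 0.392, 0.382)),
    model2 = data.frame(
      parameter = c("TVCL", "TVV", "CL_WT", "V_WT", "omega_CL", "sigma"),
      lower = c(0.684, 4.12, 0.7549, 0.585, 0.202, 0.272),
      upper = c(0.834, 5.89, 1.32, 1.29, 0.378, 0.381)),
    model3 = data.frame(
      parameter = c("TVCL", "TVV", "CL_WT", "V_WT", "CL_SCR", "omega_CL", "sigma"),
      lower = c(0.585, 2.96, 1.09, 1.06, -0.469, 0.225, 0.295),
      upper = c(0.809, 3.85, 1.36, 1.45, -0.216, 0.37, 0.37)))
}

## ---------------------------------------------------------------------------
## Maturation models
## ---------------------------------------------------------------------------

#' Weight/age maturation models for clearance screening
#'
#' The five candidate maturation structures screened before covariate search
#' (WT in kg centred at its median; age in months):
#' \describe{
#'   \item{I}{`CL = TVCL (WT/med)^m`, `V = TVV (WT/med)^n`, both exponents free.}
#'   \item{II}{`CL = TVCL (WT/med)^0.75`, `V = TVV (WT/med)` (fixed exponents).}
#'   \item{III}{`CL = TVCL (WT/med)^0.75 MF` with sigmoid maturation factor
#'     `MF = Age^Hill / (TM50^Hill + Age^Hill)` (so `MF = 0.5` at `Age = TM50`);
#'     `V` as in II.}
#'   \item{IV}{allometric exponent itself a declining sigmoid in WT:
#'     `m = theta0 - kmax WT^Hill / (k50^Hill + WT^Hill)`; `V` as in II.}
#'   \item{V}{as IV with age (months) as the sigmoid argument.}
#' }
#'
#' @param form `"I"` to `"V"`.
#' @param wt_median centering median for WT (kg).
#' @param theta optional named starting/parameter values; defaults provided.
#' @param omega,error as in [pk_model()].
#' @return A [pk_model()].
#' @export
maturation_model <- function(form = c("I", "II", "III", "IV", "V"),
                             wt_median, theta = NULL,
                             omega = c(CL = 0.3),
                             error = residual_error("proportional", 0.3)) {
  form <- match.arg(form)
  base_theta <- c(TVCL = 0.5, TVV = 3)
  v_alloc <- list(pk_term("linear_ratio", "WT", wt_median))
  spec <- switch(form,
    I = list(cl = list(pk_term("power", "WT", wt_median, "WT")),
             v = list(pk_term("power", "WT", wt_median, "WT")),
             th = c(CL_WT = 0.75, V_WT = 1)),
    II = list(cl = list(pk_term("power_fixed", "WT", wt_median,
                                fixed = list(exponent = 0.75))),
              v = v_alloc, th = NULL),
    III = list(cl = list(pk_term("power_fixed", "WT", wt_median,
                                 fixed = list(exponent = 0.75)),
                         pk_term("sigmoid_mf", "AGE", 1, c("TM50", "HILL"))),
               v = v_alloc, th = c(CL_TM50 = 2, CL_HILL = 2)),
    IV = list(cl = list(pk_term("sigmoid_exp", "WT", wt_median,
                                c("THETA0", "KMAX", "K50", "HILL"),
                                xcov = "WT")),
              v = v_alloc,
              th = c(CL_THETA0 = 1.2, CL_KMAX = 0.5, CL_K50 = wt_median,
                     CL_HILL = 2)),
    V = list(cl = list(pk_term("sigmoid_exp", "WT", wt_median,
                               c("THETA0", "KMAX", "K50", "HILL"),
                               xcov = "AGE")),
             v = v_alloc,
             th = c(CL_THETA0 = 1.2, CL_KMAX = 0.5, CL_K50 = 2, CL_HILL = 2)))
  th <- c(base_theta, spec$th)
  if (!is.null(theta)) th[names(theta)] <- theta
  pk_model(paste0("maturation-", form), spec$cl, spec$v, th, omega, error)
}

#' Clearance under a maturation form
#'
#' Direct evaluation of the clearance equation of one maturation form for given
#' covariates and maturation parameters; convenience wrapper around the term
#' machinery for screening work.
#'
#' @param form `"I"` to `"V"`.
#' @param base_tv_cl typical clearance scale TVCL (L/h).
#' @param cov data.frame with `WT` (kg) and, for forms III/V, `AGE` (months).
#' @param wt_median centering median (kg).
#' @param m allometric exponent for form I.
#' @param mat named list/vector of maturation parameters: `TM50`, `HILL` for
#'   form III; `THETA0`, `KMAX`, `K50`, `HILL` for forms IV/V.
#' @return clearance (L/h).
#' @export
maturation_cl <- function(form, base_tv_cl, cov, wt_median, m = 0.75,
                          mat = NULL) {
  form <- match.arg(form, c("I", "II", "III", "IV", "V"))
  cov <- as.data.frame(cov)
  wt_ratio <- cov$WT / wt_median
  switch(form,
    I = base_tv_cl * wt_ratio^m,
    II = base_tv_cl * wt_ratio^0.75,
    III = {
      mf <- cov$AGE^mat$HILL / (mat$TM50^mat$HILL + cov$AGE^mat$HILL)
      base_tv_cl * wt_ratio^0.75 * mf
    },
    IV = {
      mm <- mat$THETA0 - mat$KMAX * cov$WT^mat$HILL /
        (mat$K50^mat$HILL + cov$WT^mat$HILL)
      base_tv_cl * wt_ratio^mm
    },
    V = {
      mm <- mat$THETA0 - mat$KMAX * cov$AGE^mat$HILL /
        (mat$K50^mat$HILL + cov$AGE^mat$HILL)
      base_tv_cl * wt_ratio^mm
    })
}

#' Serialize / deserialize a covariate model
#'
#' Writes the model structure (terms, medians, parameter values, BSV and error
#' specification) to a JSON document and reads it back.
#'
#' @param model a [pk_model()].
#' @param path file path.
#' @return `read_pk_model()` returns the reconstructed `pk_model`.
#' @export
write_pk_model <- function(model, path) {
  ser_terms <- function(terms) lapply(terms, function(tm)
    list(type = tm$type, cov = tm$cov, median = tm$median, pars = tm$pars,
         fixed = tm$fixed, xcov = tm$xcov))
  doc <- list(name = model$name,
              cl_terms = ser_terms(model$cl_terms),
              v_terms = ser_terms(model$v_terms),
              theta = as.list(model$theta),
              omega = as.list(model$omega),
              error = list(form = model$error$form, sigma = model$error$sigma,
                           sigma2 = model$error$sigma2))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_pk_model
#' @export
read_pk_model <- function(path) {
  doc <- jsonlite::read_json(path)
  des_terms <- function(lst) lapply(lst, function(tm)
    pk_term(tm$type, tm$cov, tm$median, as.character(unlist(tm$pars)),
            lapply(tm$fixed, as.numeric),
            if (!is.null(tm$xcov)) tm$xcov))
  pk_model(doc$name, des_terms(doc$cl_terms), des_terms(doc$v_terms),
           unlist(doc$theta), unlist(doc$omega),
           residual_error(doc$error$form, doc$error$sigma,
                          if (is.null(doc$error$sigma2)) 0 else doc$error$sigma2))
}
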