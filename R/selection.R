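## ---------------------------------------------------------------------------
## Maturation-model screening and stepwise covariate search, driven by an OFV
## oracle: any function mapping a model descriptor to an objective function
## value. The oracle may be the FOCE estimator itself (make_ofv_oracle) or a
## lookup of previously computed OFVs, so a published search trace can be
## replayed exactly.
## ---------------------------------------------------------------------------

#' Chi-square deletion/addition threshold
#'
#' Upper-alpha quantile of the chi-square distribution, the likelihood-ratio
#' ΔOFV threshold for nested models differing by `df` parameters. The study's
#' defaults are `chi2_threshold(1, 0.05) = 3.84` for forward addition and
#' `chi2_threshold(1, 0.001) = 10.83` for backward elimination.
#'
#' @param df degrees of freedom (>= 1).
#' @param alpha significance level in (0, 1).
#' @return ΔOFV threshold.
#' @export
chi2_threshold <- function(df, alpha) {
  if (df < 1) stop("df must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  stats::qchisq(1 - alpha, df)
}

#' Stepwise-selection configuration
#'
#' @param forward ΔOFV required to admit a covariate (default 3.84, chi-square
#'   df = 1, p < 0.05).
#' @param backward ΔOFV below which an in-model covariate is removed again
#'   (default 10.83, chi-square df = 1, p < 0.001).
#' @return list with the two thresholds.
#' @export
selection_config <- function(forward = chi2_threshold(1, 0.05),
                             backward = chi2_threshold(1, 0.001)) {
  if (forward < 0 || backward < 0) stop("thresholds must be non-negative")
  if (backward < forward) stop("backward threshold must be >= forward threshold")
  list(forward = forward, backward = backward)
}

oracle_eval <- function(ofv_oracle, covs) {
  v <- tryCatch(ofv_oracle(covs), error = function(e) NA_real_)
  if (length(v) != 1L || !is.numeric(v)) NA_real_ else as.numeric(v)
}

#' Select the best maturation model by OFV
#'
#' Evaluates each candidate maturation form through the OFV oracle and returns
#' the form with the smallest OFV. Ties are broken by fewer estimated
#' parameters, then by listed order.
#'
#' @param forms character vector of form labels (e.g. `c("I","II","III","IV","V")`).
#' @param ofv_oracle function(form) returning the minimised OFV; failures
#'   (errors or non-numeric returns) drop the form with a warning.
#' @param n_pars optional numeric vector of estimated-parameter counts per
#'   form, used for tie-breaking; defaults to the counts of the standard forms.
#' @return list with `form` (chosen label), and `trace` (data.frame of form,
#'   OFV, parameters).
#' @export
select_maturation_model <- function(forms, ofv_oracle, n_pars = NULL) {
  if (length(forms) == 0L) stop("at least one maturation form is required")
  if (is.null(n_pars)) {
    std <- c(I = 2, II = 0, III = 2, IV = 4, V = 4)
    n_pars <- ifelse(forms %in% names(std), std[forms], 0)
  }
  ofv <- vapply(forms, function(f) oracle_eval(ofv_oracle, f), numeric(1))
  if (all(is.na(ofv))) stop("no maturation form could be evaluated")
  if (any(is.na(ofv)))
    warning("maturation form(s) failed to evaluate: ",
            paste(forms[is.na(ofv)], collapse = ", "))
  trace <- data.frame(form = forms, ofv = ofv, n_pars = n_pars)
  ok <- which(!is.na(ofv))
  best <- ok[order(ofv[ok], n_pars[ok], ok)][1L]
  list(form = forms[best], trace = trace)
}

step_record <- function(action, covariate, before, after, threshold, decision) {
  data.frame(action = action, covariate = covariate, ofv_before = before,
              ofv_after = after, delta_ofv = after - before,
              threshold = threshold, decision = decision,
              stringsAsFactors = FALSE)
}

#' Stepwise forward addition of covariates
#'
#' Starting from a base covariate set, each round evaluates every remaining
#' candidate through the OFV oracle and admits the one with the largest OFV
#' drop, provided that drop exceeds the forward threshold; the search stops
#' when no candidate qualifies. Candidates whose oracle evaluation fails are
#' skipped with a warning, never silently admitted.
#'
#' @param base character vector, the starting covariate set (may be empty; a
#'   structural `"WT"` allometry is typically part of it).
#' @param candidates character vector of candidate covariates.
#' @param config a [selection_config()].
#' @param ofv_oracle function(covariate-set) returning the minimised OFV.
#' @return list of class `"selection_trace"`: `steps` (data.frame, one row per
#'   evaluated candidate with the decision), `selected` (final covariate set),
#'   `ofv` (final OFV).
#' @export
forward_search <- function(base, candidates, config = selection_config(),
                           ofv_oracle) {
  current <- base
  current_ofv <- oracle_eval(ofv_oracle, current)
  if (is.na(current_ofv)) stop("base model could not be evaluated")
  steps <- NULL
  remaining <- setdiff(candidates, base)
  repeat {
    if (length(remaining) == 0L) break
    ofvs <- vapply(remaining, function(cv)
      oracle_eval(ofv_oracle, c(current, cv)), numeric(1))
    if (any(is.na(ofvs)))
      warning("candidate(s) skipped (oracle failure): ",
              paste(remaining[is.na(ofvs)], collapse = ", "))
    drops <- current_ofv - ofvs
    best <- which(!is.na(ofvs))[order(-drops[!is.na(ofvs)])][1L]
    admitted <- !is.na(best) && drops[best] > config$forward
    round_steps <- step_record("add", remaining, current_ofv, ofvs,
                               config$forward,
                               ifelse(seq_along(remaining) == ifelse(admitted, best, 0L),
                                      "admitted", "rejected"))
    steps <- rbind(steps, round_steps)
    if (!admitted) break
    current <- c(current, remaining[best])
    current_ofv <- unname(ofvs[best])
    remaining <- remaining[-best]
  }
  structure(list(steps = steps, selected = current, ofv = current_ofv),
            class = "selection_trace")
}

#' Stepwise backward elimination of covariates
#'
#' Each round removes the in-model covariate whose exclusion raises the OFV
#' the least, provided that rise stays below the backward threshold; the
#' procedure repeats until every removal would raise the OFV by at least the
#' threshold. Only covariates listed in `removable` are candidates for
#' exclusion (a structural weight allometry is removable only when listed).
#'
#' @param full character vector, the full covariate set after forward search.
#' @param removable covariates that may be excluded (default: all of `full`).
#' @param config a [selection_config()].
#' @param ofv_oracle function(covariate-set) returning the minimised OFV.
#' @return A `"selection_trace"` as in [forward_search()].
#' @export
backward_elimination <- function(full, removable = full,
                                 config = selection_config(), ofv_oracle) {
  current <- full
  current_ofv <- oracle_eval(ofv_oracle, current)
  if (is.na(current_ofv)) stop("full model could not be evaluated")
  steps <- NULL
  repeat {
    cand <- intersect(removable, current)
    if (length(cand) == 0L) break
    ofvs <- vapply(cand, function(cv)
      oracle_eval(ofv_oracle, setdiff(current, cv)), numeric(1))
    if (any(is.na(ofvs)))
      warning("removal(s) skipped (oracle failure): ",
              paste(cand[is.na(ofvs)], collapse = ", "))
    rises <- ofvs - current_ofv
    ok <- which(!is.na(ofvs))
    if (length(ok) == 0L) break
    best <- ok[order(rises[ok])][1L]
    removed <- rises[best] < config$backward
    round_steps <- step_record("remove", cand, current_ofv, ofvs,
                               config$backward,
                               ifelse(seq_along(cand) == ifelse(removed, best, 0L),
                                      "removed", "retained"))
    steps <- rbind(steps, round_steps)
    if (!removed) break
    current <- setdiff(current, cand[best])
    current_ofv <- unname(ofvs[best])
  }
  structure(list(steps = steps, selected = current, ofv = current_ofv),
            class = "selection_trace")
}

#' @export
print.selection_trace <- function(x, ...) {
  cat("Stepwise covariate search\n")
  if (!is.null(x$steps)) print(x$steps, row.names = FALSE)
  cat("final set: {", paste(x$selected, collapse = ", "), "}  OFV =",
      round(x$ofv, 3), "\n")
  invisible(x)
}

#' Serialize a selection trace to JSON
#'
#' @param trace a `"selection_trace"`.
#' @param path output path.
#' @export
write_selection_trace <- function(trace, path) {
  jsonlite::write_json(list(steps = trace$steps, selected = trace$selected,
                            ofv = trace$ofv),
                       path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}

#' OFV oracle backed by the FOCE estimator
#'
#' Builds, for a covariate set, the corresponding model (structural weight
#' allometry on CL and V with free exponents when `"WT"` is in the set;
#' continuous covariates as exponential-slope terms `exp(theta COV/median)` on
#' CL; binary covariates as `exp(theta COV)` on CL) and returns its minimised
#' FOCE OFV. Medians are taken from the dataset.
#'
#' @param data an event-table dataset.
#' @param binary covariate names treated as binary flags.
#' @param control passed to [pkfit()].
#' @return function(covariate-set) -> OFV, suitable for [forward_search()]
#'   and [backward_elimination()].
#' @export
make_ofv_oracle <- function(data, binary = c("SEX", "PRETERM", "COMED"),
                            control = pkfit_control()) {
  design <- pk_design(data)
  meds <- vapply(design$cov, function(x) stats::median(as.numeric(x)),
                 numeric(1))
  function(covs) {
    cl_terms <- list()
    v_terms <- list()
    theta <- c(TVCL = 0.5, TVV = 3)
    if ("WT" %in% covs) {
      cl_terms <- c(cl_terms, list(pk_term("power", "WT", meds[["WT"]], "WT")))
      v_terms <- c(v_terms, list(pk_term("power", "WT", meds[["WT"]], "WT")))
      theta <- c(theta, CL_WT = 1, V_WT = 1)
    }
    for (cv in setdiff(covs, "WT")) {
      med <- if (cv %in% binary) 1 else meds[[cv]]
      cl_terms <- c(cl_terms, list(pk_term("expslope", cv, med, cv)))
      theta[paste0("CL_", cv)] <- 0
    }
    mod <- pk_model(paste(c("cov", covs), collapse = "+"), cl_terms, v_terms,
                    theta, omega = c(CL = 0.3),
                    error = residual_error("proportional", 0.3))
    fit <- pkfit(data, mod, control = control)
    fit$ofv
  }
}
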