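#' Dosing events for intravenous infusions
#'
#' Constructs a table of zero-order intravenous infusion events. Times are in
#' hours since the first dose, amounts in mg, durations in hours.
#'
#' @param start_time numeric vector, infusion start times (h), `>= 0`.
#' @param amount numeric vector, dose amounts (mg), `> 0`.
#' @param duration numeric vector, infusion durations (h), `> 0`. Recycled.
#'   Defaults to 1 h, the minimum infusion length of the dosing protocol.
#' @return A `data.frame` with columns `start_time`, `amount`, `duration`,
#'   sorted by `start_time`.
#' @examples
#' dosing_events(start_time = c(0, 8, 16), amount = 60)
#' @export
dosing_events <- function(start_time, amount, duration = 1) {
  ev <- data.frame(start_time = as.numeric(start_time),
                   amount = as.numeric(amount),
                   duration = as.numeric(duration))
  if (any(!is.finite(ev$start_time)) || any(ev$start_time < 0))
    stop("infusion start times must be finite and >= 0")
  if (any(!is.finite(ev$amount)) || any(ev$amount <= 0))
    stop("dose amounts must be finite and > 0")
  if (any(!is.finite(ev$duration)) || any(ev$duration <= 0))
    stop("infusion durations must be finite and > 0")
  ev[order(ev$start_time), , drop = FALSE]
}

check_ind_params <- function(cl, v) {
  if (any(!is.finite(cl)) || any(cl <= 0)) stop("CL must be finite and > 0")
  if (any(!is.finite(v)) || any(v <= 0)) stop("V must be finite and > 0")
  invisible(TRUE)
}

#' Concentration from a single intravenous infusion
#'
#' Closed-form one-compartment, first-order-elimination concentration for one
#' zero-order infusion. During the infusion
#' \eqn{C(t) = (R_0/CL)(1 - e^{-k(t - t_0)})} with infusion rate
#' \eqn{R_0 = \mathrm{amount}/\mathrm{duration}} and \eqn{k = CL/V}; after the
#' infusion ends the end-of-infusion concentration decays as \eqn{e^{-k\Delta t}}.
#' Before the infusion starts the concentration is 0.
#'
#' @param t numeric vector of times (h since first dose), `>= 0`.
#' @param event a single-row event as from [dosing_events()] (or a list with
#'   `start_time`, `amount`, `duration`).
#' @param cl clearance (L/h), `> 0`.
#' @param v volume of distribution (L), `> 0`.
#' @return Concentrations (mg/L) at `t`.
#' @examples
#' ev <- dosing_events(0, 60, 1)
#' single_infusion_concentration(1, ev, cl = 0.756, v = 4.89)
#' @export
single_infusion_concentration <- function(t, event, cl, v) {
  check_ind_params(cl, v)
  if (length(event$start_time) != 1L) stop("'event' must be a single dosing event")
  if (event$duration <= 0) stop("infusion duration must be > 0")
  if (any(t < 0)) stop("t must be >= 0")
  conc_pairs(t - event$start_time, event$amount, event$duration, cl, v)
}

# Vectorised kernel: concentration contribution of one infusion observed a lag
# `dt` after its start. All arguments recycled to common length.
conc_pairs <- function(dt, amount, duration, cl, v) {
  k <- cl / v
  r0 <- amount / duration
  te <- pmin(pmax(dt, 0), duration)           # elapsed infusion time
  decay <- exp(-k * pmax(dt - duration, 0))   # post-infusion decay
  out <- (r0 / cl) * (1 - exp(-k * te)) * decay
  out[dt <= 0] <- 0
  out
}

#' Concentration under multiple infusions by superposition
#'
#' Sums [single_infusion_concentration()] over all dosing events (the system is
#' linear, so concurrent infusion rates add).
#'
#' @inheritParams single_infusion_concentration
#' @param events event table from [dosing_events()]; may be empty (returns 0).
#' @return Concentrations (mg/L) at `t`.
#' @examples
#' ev <- dosing_events(seq(0, 32, by = 8), 60)
#' concentration_at(31.5, ev, cl = 0.756, v = 4.89)
#' @export
concentration_at <- function(t, events, cl, v) {
  check_ind_params(cl, v)
  if (any(t < 0)) stop("t must be >= 0")
  if (is.null(events) || nrow(events) == 0L) return(numeric(length(t)))
  dt <- outer(t, events$start_time, "-")
  contrib <- conc_pairs(as.vector(dt),
                        rep(events$amount, each = length(t)),
                        rep(events$duration, each = length(t)),
                        cl, v)
  rowSums(matrix(contrib, nrow = length(t)))
}

#' Numerical ODE reference for the infusion model
#'
#' Integrates \eqn{dA/dt = \mathrm{rate_{in}}(t) - k A} with
#' \eqn{\mathrm{rate_{in}}} piecewise constant over the infusion schedule and
#' returns \eqn{A(t)/V}. The integration proceeds segment by segment between
#' rate breakpoints (deSolve::lsoda), so the discontinuous input is handled
#' exactly. Intended as an independent numerical reference for
#' [concentration_at()].
#'
#' @inheritParams concentration_at
#' @param rtol,atol integrator tolerances.
#' @return Concentrations (mg/L) at `t`.
#' @export
ode_oracle_concentration <- function(t, events, cl, v,
                                     rtol = 1e-10, atol = 1e-12) {
  check_ind_params(cl, v)
  if (any(t < 0)) stop("t must be >= 0")
  if (is.null(events) || nrow(events) == 0L) return(numeric(length(t)))
  k <- cl / v
  brk <- sort(unique(c(0, events$start_time, events$start_time + events$duration, t)))
  rate_at <- function(tm) {
    on <- tm >= events$start_time & tm < events$start_time + events$duration
    sum(events$amount[on] / events$duration[on])
  }
  amt <- numeric(length(brk))
  a0 <- 0
  for (i in seq_len(length(brk) - 1L)) {
    r <- rate_at((brk[i] + brk[i + 1L]) / 2)  # constant within the segment
    sol <- deSolve::lsoda(
      y = c(A = a0), times = c(brk[i], brk[i + 1L]),
      func = function(tt, y, p) list(r - k * y[1L]),
      rtol = rtol, atol = atol)
    if (any(is.na(sol)))
      stop("ODE integration failed on segment [", brk[i], ", ", brk[i + 1L], "]")
    a0 <- unname(sol[nrow(sol), 2L])
    amt[i + 1L] <- a0
  }
  amt[match(t, brk)] / v
}
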