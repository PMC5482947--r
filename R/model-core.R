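## Core glucose-insulin compartment model: right-hand side, steady state of
## the insulin subsystem, and forward simulation with exact restarts at every
## piecewise-constant input or SI discontinuity.

#' Model state
#'
#' @param G blood glucose (mmol/L)
#' @param I plasma insulin (mU/L)
#' @param Q interstitial insulin (mU/L)
#' @param t time (min)
#' @return An object of class `model_state`.
#' @export
model_state <- function(G, I, Q, t = 0) {
  for (f in c("G", "I", "Q", "t")) {
    v <- get(f)
    if (!.is_number(v)) .stopf("state field '%s' must be a single finite number", f)
  }
  if (G < 0 || I < 0 || Q < 0) .stopf("state fields G, I, Q must be >= 0")
  structure(list(G = G, I = I, Q = Q, t = t), class = "model_state")
}

#' Model right-hand side
#'
#' Time derivatives of the three compartments under instantaneous inputs.
#' Glucose is cleared at the endogenous rate `p_G` and by saturable
#' insulin-mediated uptake scaled by SI; plasma insulin is cleared renally
#' (`n_K`), hepatically (saturable, `n_L`) and by transfer to the interstitium
#' (`n_I`); interstitial insulin degrades saturably (`n_C`). All clearance
#' terms act as losses; the `printed_nk_sign` audit flag in the parameters
#' flips the renal term's sign.
#'
#' @param state a [model_state()] (or a named list with fields G, I, Q)
#' @param params an [icing_params()] object
#' @param si insulin sensitivity (L/mU/min), `>= 0`
#' @param u_ex exogenous insulin rate (mU/min)
#' @param P glucose appearance from dextrose (mmol/min)
#' @return named numeric vector `c(dG, dI, dQ)` (per minute)
#' @export
icing_rhs <- function(state, params, si, u_ex, P) {
  for (f in c("G", "I", "Q")) {
    if (!.is_number(state[[f]])) {
      .stopf("state field '%s' must be a single finite number", f)
    }
  }
  if (!.is_number(si) || si < 0) .stopf("si must be a single finite number >= 0")
  if (!.is_number(u_ex) || u_ex < 0) .stopf("u_ex must be a single finite number >= 0")
  if (!.is_number(P) || P < 0) .stopf("P must be a single finite number >= 0")
  validate_icing_params(params)
  .icing_deriv(c(state$G, state$I, state$Q), params, si, u_ex, P)
}

## Unchecked fast path shared by the integrators.
.icing_deriv <- function(y, params, si, u_ex, P) {
  G <- y[[1L]]; I <- y[[2L]]; Q <- y[[3L]]
  Qeff <- Q / (1 + params$alpha_G * Q)
  dG <- -params$p_G * G - si * G * Qeff +
    (P + params$EGP - params$CNS) / params$V_G
  nk_term <- params$n_K * I
  if (isTRUE(params$printed_nk_sign)) nk_term <- -nk_term
  dI <- -nk_term - params$n_L * I / (1 + params$alpha_I * I) -
    params$n_I * (I - Q) + u_ex / params$V_I +
    (1 - params$x_L) * u_en_rate(G, params) / params$V_I
  dQ <- params$n_I * (I - Q) - params$n_C * Qeff
  c(dG = dG, dI = dI, dQ = dQ)
}

#' Steady state of the insulin subsystem at fixed glucose
#'
#' Solves `dI/dt = dQ/dt = 0` for plasma and interstitial insulin at a given
#' blood glucose and constant exogenous insulin rate. Used to hot-start the
#' compartments of simulated and identified records at a physiologically
#' consistent point.
#'
#' @param G blood glucose (mmol/L)
#' @param u_ex exogenous insulin rate (mU/min)
#' @param params an [icing_params()] object
#' @return named numeric vector `c(I, Q)` (mU/L)
#' @export
steady_insulin_state <- function(G, u_ex, params) {
  src <- (u_ex + (1 - params$x_L) * u_en_rate(G, params)) / params$V_I
  if (src <= 0) return(c(I = 0, Q = 0))
  I_of_Q <- function(Q) Q + (params$n_C / params$n_I) * Q / (1 + params$alpha_G * Q)
  resid <- function(Q) {
    I <- I_of_Q(Q)
    nk_term <- params$n_K * I
    if (isTRUE(params$printed_nk_sign)) nk_term <- -nk_term
    -nk_term - params$n_L * I / (1 + params$alpha_I * I) -
      params$n_I * (I - Q) + src
  }
  hi <- 1
  while (resid(hi) > 0 && hi < 1e9) hi <- hi * 10
  if (resid(hi) > 0) .stopf("insulin subsystem has no steady state for these parameters")
  Q <- stats::uniroot(resid, c(0, hi), tol = 1e-12)$root
  c(I = I_of_Q(Q), Q = Q)
}

#' Forward simulation of the glucose-insulin model
#'
#' Integrates the model with a stiff-capable adaptive solver
#' ([deSolve::lsoda]), restarting at every discontinuity of the input schedule
#' or the hourly SI trajectory so that piecewise-constant steps are honoured
#' exactly. Tolerances are `atol = 1e-8`, `rtol = 1e-6`; tiny negative
#' excursions are clamped to zero on output.
#'
#' @param init a [model_state()] giving the state at `t = 0`
#' @param params an [icing_params()] object
#' @param si an [si_trajectory()] covering the horizon
#' @param schedule an [input_schedule()] covering the horizon
#' @param horizon simulation length (min)
#' @param output_dt spacing of the output grid (min); output times are
#'   `seq(0, horizon, by = output_dt)`
#' @param rtol,atol solver tolerances
#' @return data.frame with columns `time_min`, `G`, `I`, `Q`
#' @export
simulate_icing <- function(init, params, si, schedule, horizon,
                           output_dt = 1, rtol = 1e-6, atol = 1e-8) {
  validate_icing_params(params)
  if (!inherits(si, "si_trajectory")) si <- si_trajectory(si)
  if (!inherits(schedule, "input_schedule")) .stopf("schedule must be an input_schedule")
  if (!.is_number(horizon) || horizon <= 0) .stopf("horizon must be a positive number")
  covered <- (si$start_hour + length(si$values)) * 60
  if (covered < horizon) {
    .stopf("si trajectory covers only %g min of the %g-min horizon", covered, horizon)
  }
  grid <- seq(0, horizon, by = output_dt)
  if (grid[length(grid)] < horizon) grid <- c(grid, horizon)
  breaks <- .breakpoints(schedule, si, horizon)

  y <- c(G = init$G, I = init$I, Q = init$Q)
  out <- matrix(NA_real_, nrow = length(grid), ncol = 3L,
                dimnames = list(NULL, c("G", "I", "Q")))
  out[1L, ] <- y
  deriv <- function(t, y, parms) {
    list(.icing_deriv(y, params, parms$si, parms$u_ex, parms$P))
  }
  for (k in seq_len(length(breaks) - 1L)) {
    t0 <- breaks[k]; t1 <- breaks[k + 1L]
    mid <- (t0 + t1) / 2
    inp <- schedule_at(schedule, mid)
    parms <- list(si = si_at(si, mid), u_ex = inp$u_ex, P = inp$P)
    keep <- grid[grid > t0 & grid <= t1]
    times <- sort(unique(c(t0, keep, t1)))
    sol <- deSolve::lsoda(y, times, deriv, parms, rtol = rtol, atol = atol)
    if (attr(sol, "istate")[1L] < 0 || any(!is.finite(sol[, -1L]))) {
      .stopf("integration failed near t = %g min", t0)
    }
    if (any(sol[, -1L] < -1e-6)) {
      .stopf("state blow-up (negative compartment) near t = %g min", t0)
    }
    if (length(keep)) {
      out[match(keep, grid), ] <- sol[match(keep, sol[, "time"]), c("G", "I", "Q")]
    }
    y <- sol[nrow(sol), c("G", "I", "Q")]
    y <- pmax(y, 0)  # guard restarts against roundoff-level negatives
  }
  data.frame(time_min = grid, G = pmax(out[, "G"], 0),
             I = pmax(out[, "I"], 0), Q = pmax(out[, "Q"], 0))
}

#' Write a simulated trajectory to CSV
#'
#' @param trajectory data.frame as returned by [simulate_icing()]
#' @param path output path
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  stopifnot(all(c("time_min", "G", "I", "Q") %in% names(trajectory)))
  utils::write.csv(trajectory[, c("time_min", "G", "I", "Q")], path,
                   row.names = FALSE)
  invisible(path)
}
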