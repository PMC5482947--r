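## Hourly identification of insulin sensitivity by the integral method.
## The plasma/interstitial insulin equations do not involve SI, so the insulin
## compartments are simulated once (driven by interpolated BG through the
## endogenous-secretion term), after which integrating the glucose equation
## over each therapy-anchored hour gives a closed-form linear solve for SI.

#' Piecewise-linear interpolation of blood glucose measurements
#'
#' @param bg data.frame with columns `time` (min) and `value` (mmol/L)
#' @param grid query times (min); must lie within the measurement span
#' @return numeric vector of interpolated glucose values
#' @export
interpolate_bg <- function(bg, grid) {
  if (nrow(bg) < 2L) .stopf("need >= 2 BG measurements to interpolate")
  if (min(grid) < min(bg$time) - 1e-9 || max(grid) > max(bg$time) + 1e-9) {
    .stopf("interpolation grid [%g, %g] outside measurement span [%g, %g]",
           min(grid), max(grid), min(bg$time), max(bg$time))
  }
  stats::approx(bg$time, bg$value, xout = grid, method = "linear",
                rule = 2)$y
}

## Classical RK4 for the SI-free insulin subsystem on a fixed grid, with the
## exogenous rate held piecewise-constant and G given on the grid (linearly
## interpolated at half-steps). The 1-min identification grid keeps the local
## error far below the data-driven identification error.
.integrate_insulin <- function(grid, G, u_ex, params) {
  n <- length(grid)
  I <- numeric(n); Q <- numeric(n)
  s0 <- steady_insulin_state(G[1L], 0, params)
  I[1L] <- s0[["I"]]; Q[1L] <- s0[["Q"]]
  a_G <- params$alpha_G; a_I <- params$alpha_I
  nK <- params$n_K; nL <- params$n_L; nI <- params$n_I; nC <- params$n_C
  nk_sign <- if (isTRUE(params$printed_nk_sign)) 1 else -1
  ## the insulin source depends on time only through u_ex and u_en(G(t)):
  ## precompute it on the grid (and at interval midpoints for RK4 half-steps).
  ## u_ex is piecewise constant on half-open steps, so within interval
  ## [k, k+1) the left value applies everywhere, including the k4 endpoint.
  uen <- (1 - params$x_L) * u_en_rate(G, params) / params$V_I
  uen_mid <- (1 - params$x_L) *
    u_en_rate((G[-n] + G[-1L]) / 2, params) / params$V_I
  uex_v <- u_ex / params$V_I
  for (k in seq_len(n - 1L)) {
    h <- grid[k + 1L] - grid[k]
    s0v <- uex_v[k] + uen[k]
    smv <- uex_v[k] + uen_mid[k]
    s1v <- uex_v[k] + uen[k + 1L]
    i0 <- I[k]; q0 <- Q[k]
    d1i <- nk_sign * nK * i0 - nL * i0 / (1 + a_I * i0) - nI * (i0 - q0) + s0v
    d1q <- nI * (i0 - q0) - nC * q0 / (1 + a_G * q0)
    i1 <- i0 + h / 2 * d1i; q1 <- q0 + h / 2 * d1q
    d2i <- nk_sign * nK * i1 - nL * i1 / (1 + a_I * i1) - nI * (i1 - q1) + smv
    d2q <- nI * (i1 - q1) - nC * q1 / (1 + a_G * q1)
    i2 <- i0 + h / 2 * d2i; q2 <- q0 + h / 2 * d2q
    d3i <- nk_sign * nK * i2 - nL * i2 / (1 + a_I * i2) - nI * (i2 - q2) + smv
    d3q <- nI * (i2 - q2) - nC * q2 / (1 + a_G * q2)
    i3 <- i0 + h * d3i; q3 <- q0 + h * d3q
    d4i <- nk_sign * nK * i3 - nL * i3 / (1 + a_I * i3) - nI * (i3 - q3) + s1v
    d4q <- nI * (i3 - q3) - nC * q3 / (1 + a_G * q3)
    I[k + 1L] <- max(0, i0 + h / 6 * (d1i + 2 * d2i + 2 * d3i + d4i))
    Q[k + 1L] <- max(0, q0 + h / 6 * (d1q + 2 * d2q + 2 * d3q + d4q))
  }
  list(I = I, Q = Q)
}

## Exact integral of the piecewise-constant appearance rate P over [a, b].
.integrate_schedule_P <- function(schedule, a, b) {
  ## step i is active on [bounds[i], bounds[i+1]); rates before the first
  ## step time take the first value, matching schedule_at()
  bounds <- c(-Inf, schedule$times[-1L], Inf)
  tot <- 0
  for (i in seq_along(schedule$P)) {
    lo <- max(a, bounds[i]); hi <- min(b, bounds[i + 1L])
    if (hi > lo) tot <- tot + schedule$P[i] * (hi - lo)
  }
  tot
}

#' Simulate the SI-free insulin compartments of a record
#'
#' Plasma and interstitial insulin are independent of SI, so they can be
#' simulated directly from the record's insulin schedule, with endogenous
#' secretion evaluated on the interpolated blood glucose. The compartments are
#' hot-started at the endogenous-only steady state for the first measured BG.
#'
#' @param record a [patient_record()]
#' @param params an [icing_params()] object
#' @param grid optional integration grid (min); defaults to a 1-min grid over
#'   the record's BG span from therapy start
#' @return data.frame with columns `time`, `I`, `Q`
#' @export
simulate_insulin_compartments <- function(record, params, grid = NULL) {
  validate_icing_params(params)
  if (is.null(grid)) {
    t0 <- max(record$therapy_start, min(record$bg$time))
    grid <- seq(t0, max(record$bg$time), by = 1)
  }
  G <- interpolate_bg(record$bg, grid)
  sched <- record_schedule(record)
  u_ex <- schedule_at(sched, grid)$u_ex
  iq <- .integrate_insulin(grid, G, u_ex, params)
  data.frame(time = grid, I = iq$I, Q = iq$Q)
}

## Shared identification context: 1-min grid aligned to therapy-anchored hour
## boundaries, interpolated BG, simulated insulin compartments.
.si_fit_context <- function(record, params, horizon_hours) {
  if (nrow(record$bg) < 2L) {
    .stopf("patient %s: need >= 2 BG measurements to identify SI",
           record$patient_id)
  }
  t0 <- record$therapy_start
  lo <- max(t0, min(record$bg$time))
  hi <- min(t0 + horizon_hours * 60, max(record$bg$time))
  h_first <- ceiling((lo - t0) / 60 - 1e-9)
  h_last_end <- floor((hi - t0) / 60 + 1e-9)  # last covered hour boundary
  if (h_last_end <= h_first) {
    return(list(hours = integer(0)))
  }
  grid <- seq(t0 + 60 * h_first, t0 + 60 * h_last_end, by = 1)
  G <- interpolate_bg(record$bg, grid)
  sched <- record_schedule(record)
  u_ex <- schedule_at(sched, grid)$u_ex
  iq <- .integrate_insulin(grid, G, u_ex, params)
  list(hours = h_first:(h_last_end - 1L), t0 = t0, h_first = h_first,
       grid = grid, G = G, Q = iq$Q, sched = sched)
}

.fit_hour_in_context <- function(ctx, params, hour, si_min, denom_eps) {
  i0 <- (hour - ctx$h_first) * 60 + 1L
  idx <- i0:(i0 + 60L)
  tt <- ctx$grid[idx]; G <- ctx$G[idx]; Q <- ctx$Q[idx]
  Qeff <- Q / (1 + params$alpha_G * Q)
  denom <- .trapz(tt, G * Qeff)
  if (!is.finite(denom) || denom < denom_eps) {
    return(list(si = NA_real_, flag = "unidentifiable"))
  }
  dG <- G[length(G)] - G[1L]
  int_G <- .trapz(tt, G)
  appearance <- (.integrate_schedule_P(ctx$sched, tt[1L], tt[length(tt)]) +
                   (params$EGP - params$CNS) * 60) / params$V_G
  si <- (-dG - params$p_G * int_G + appearance) / denom
  if (si < si_min) list(si = si_min, flag = "clamped") else list(si = si, flag = "ok")
}

#' Identify SI for a single therapy-anchored hour
#'
#' Integrating the glucose equation over the half-open hour `[h, h+1)` (from
#' therapy start) with piecewise-linear interpolated BG makes SI the only
#' unknown and gives the closed-form solve
#' `SI = (-dG - p_G*int(G) + int((P+EGP-CNS)/V_G)) / int(G*Q/(1+alpha_G*Q))`,
#' with all integrals evaluated by composite trapezoid on a 1-min grid (the
#' nutrition integral is computed exactly from the step schedule). A negative
#' solution is clamped to `si_min` and flagged; a vanishing denominator (no
#' effective insulin) is flagged unidentifiable.
#'
#' @param record a [patient_record()]
#' @param params an [icing_params()] object
#' @param hour 0-based hour index from therapy start
#' @param si_min clamp floor (L/mU/min)
#' @param denom_eps threshold below which the denominator integral is treated
#'   as no effective insulin
#' @return list with elements `si` (L/mU/min, `NA` if unidentifiable) and
#'   `flag` (`"ok"`, `"clamped"` or `"unidentifiable"`)
#' @export
fit_si_hour <- function(record, params, hour, si_min = 1e-8,
                        denom_eps = 1e-2) {
  ctx <- .si_fit_context(record, params, horizon_hours = hour + 1L)
  if (!(hour %in% ctx$hours)) {
    .stopf("patient %s: hour %d is not fully covered by BG data",
           record$patient_id, hour)
  }
  .fit_hour_in_context(ctx, params, hour, si_min, denom_eps)
}

#' Identify the hourly SI profile of a record
#'
#' Applies the hourly integral solve to every whole therapy-anchored hour with
#' BG coverage in `0 .. horizon_hours - 1`. Hours without full BG coverage are
#' absent from the result (never imputed).
#'
#' @inheritParams fit_si_hour
#' @param horizon_hours analysis horizon in hours from therapy start
#' @return An `si_profile`: a data.frame with columns `patient_id`, `hour`,
#'   `si`, `flag`.
#' @export
fit_si_profile <- function(record, params, horizon_hours = 72,
                           si_min = 1e-8, denom_eps = 1e-2) {
  ctx <- .si_fit_context(record, params, horizon_hours)
  fits <- lapply(ctx$hours, function(h) {
    .fit_hour_in_context(ctx, params, h, si_min, denom_eps)
  })
  out <- data.frame(
    patient_id = rep(record$patient_id, length(ctx$hours)),
    hour = as.integer(ctx$hours),
    si = vapply(fits, function(f) f$si, numeric(1)),
    flag = vapply(fits, function(f) f$flag, character(1)),
    stringsAsFactors = FALSE
  )
  class(out) <- c("si_profile", "data.frame")
  out
}

#' Write SI profiles to CSV
#'
#' Columns: `patient_id`, `hour`, `si`, `flag`.
#'
#' @param profiles an `si_profile` or a list of them
#' @param path output path
#' @return `path`, invisibly.
#' @export
write_si_profiles_csv <- function(profiles, path) {
  if (inherits(profiles, "si_profile")) profiles <- list(profiles)
  utils::write.csv(do.call(rbind, lapply(profiles, as.data.frame)), path,
                   row.names = FALSE)
  invisible(path)
}

#' Read SI profiles from CSV
#'
#' @param path CSV path with columns `patient_id`, `hour`, `si`, `flag`
#' @return named list of `si_profile` objects, one per patient.
#' @export
read_si_profiles_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(split(d, d$patient_id), function(x) {
    x <- x[order(x$hour), c("patient_id", "hour", "si", "flag")]
    rownames(x) <- NULL
    class(x) <- c("si_profile", "data.frame")
    x
  })
}
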