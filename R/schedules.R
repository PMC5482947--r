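## Piecewise-constant model inputs (exogenous insulin and glucose appearance)
## and the piecewise-constant hourly SI trajectory. Steps are half-open
## intervals [t_i, t_{i+1}); times are minutes.

#' Piecewise-constant exogenous input schedule
#'
#' Exogenous insulin and dextrose appearance are held constant on half-open
#' steps `[times[i], times[i+1])`; the final step extends to the simulation
#' horizon.
#'
#' @param times strictly increasing step start times (min)
#' @param u_ex exogenous insulin rate on each step (mU/min)
#' @param P glucose appearance from enteral/parenteral dextrose on each step
#'   (mmol/min)
#' @return An object of class `input_schedule`.
#' @export
input_schedule <- function(times, u_ex, P) {
  if (length(times) < 1L) .stopf("input_schedule needs at least one step")
  if (length(u_ex) != length(times) || length(P) != length(times)) {
    .stopf("times, u_ex and P must have equal length")
  }
  if (any(!is.finite(times)) || any(!is.finite(u_ex)) || any(!is.finite(P))) {
    .stopf("input_schedule fields must be finite")
  }
  if (any(diff(times) <= 0)) .stopf("step times must be strictly increasing")
  if (any(u_ex < 0) || any(P < 0)) .stopf("input rates must be >= 0")
  structure(list(times = as.numeric(times), u_ex = as.numeric(u_ex),
                 P = as.numeric(P)),
            class = "input_schedule")
}

#' Evaluate an input schedule
#'
#' @param schedule an `input_schedule`
#' @param t times (min), vectorised; times before the first step take the
#'   first step's rates
#' @return data.frame with columns `u_ex` and `P`
#' @export
schedule_at <- function(schedule, t) {
  i <- findInterval(t, schedule$times)
  i[i < 1L] <- 1L
  data.frame(u_ex = schedule$u_ex[i], P = schedule$P[i])
}

#' Hourly piecewise-constant insulin-sensitivity trajectory
#'
#' SI is constant on half-open hours `[start_hour + k, start_hour + k + 1)`.
#'
#' @param values SI per hour (L/mU/min), non-negative and finite
#' @param start_hour 0-based integer hour index of the first value
#' @return An object of class `si_trajectory`.
#' @export
si_trajectory <- function(values, start_hour = 0L) {
  if (!length(values)) .stopf("si_trajectory needs at least one value")
  if (any(!is.finite(values)) || any(values < 0)) {
    .stopf("SI values must be finite and >= 0")
  }
  structure(list(values = as.numeric(values),
                 start_hour = as.integer(start_hour)),
            class = "si_trajectory")
}

#' Evaluate an SI trajectory at arbitrary times
#'
#' @param si an `si_trajectory`
#' @param t_min times in minutes, vectorised; times outside the covered span
#'   take the nearest endpoint value
#' @return numeric vector of SI values (L/mU/min)
#' @export
si_at <- function(si, t_min) {
  h <- floor(t_min / 60) - si$start_hour
  idx <- .clamp(h + 1, 1, length(si$values))
  si$values[idx]
}

## Merged, sorted breakpoints of a schedule and an SI trajectory over
## [0, horizon]: integration restarts at each to honour the steps exactly.
.breakpoints <- function(schedule, si, horizon) {
  hrs <- (si$start_hour + seq_len(length(si$values)) - 1L) * 60
  b <- sort(unique(c(0, schedule$times, hrs, horizon)))
  b[b >= 0 & b <= horizon]
}
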