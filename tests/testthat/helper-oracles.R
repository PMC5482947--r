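## Independent oracles used across the suite. Every oracle re-types the model
## equations or statistic from scratch rather than calling package internals,
## so agreement is a genuine cross-check.

## Explicit-Euler integration of the full three-compartment model.
## si_vals: hourly values from t = 0; u_fun/P_fun: functions of time (min).
oracle_euler_icing <- function(y0, params, si_vals, u_fun, P_fun,
                               horizon, dt = 0.01, keep = NULL) {
  p <- params
  if (is.null(keep)) keep <- horizon
  out <- matrix(NA_real_, length(keep), 3L,
                dimnames = list(NULL, c("G", "I", "Q")))
  y <- y0
  t <- 0
  ki <- 1L
  n <- round(horizon / dt)
  for (s in seq_len(n)) {
    G <- y[1L]; I <- y[2L]; Q <- y[3L]
    si <- si_vals[min(length(si_vals), floor(t / 60) + 1L)]
    uen <- min(p$u_en_max, max(p$u_en_basal, p$u_en_slope * G + p$u_en_intercept))
    dG <- -p$p_G * G - si * G * Q / (1 + p$alpha_G * Q) +
      (P_fun(t) + p$EGP - p$CNS) / p$V_G
    dI <- -p$n_K * I - p$n_L * I / (1 + p$alpha_I * I) - p$n_I * (I - Q) +
      u_fun(t) / p$V_I + (1 - p$x_L) * uen / p$V_I
    dQ <- p$n_I * (I - Q) - p$n_C * Q / (1 + p$alpha_G * Q)
    y <- y + dt * c(dG, dI, dQ)
    t <- t + dt
    while (ki <= length(keep) && t >= keep[ki] - dt / 2) {
      out[ki, ] <- y
      ki <- ki + 1L
    }
  }
  out
}

## Algebraic steady state of the full model under constant inputs, found by
## multivariate root finding (pracma::fsolve) on re-typed residuals.
oracle_steady_state <- function(params, si, u_ex, P, guess = c(6, 20, 10)) {
  p <- params
  f <- function(y) {
    G <- y[1L]; I <- y[2L]; Q <- y[3L]
    uen <- min(p$u_en_max, max(p$u_en_basal, p$u_en_slope * G + p$u_en_intercept))
    c(-p$p_G * G - si * G * Q / (1 + p$alpha_G * Q) + (P + p$EGP - p$CNS) / p$V_G,
      -p$n_K * I - p$n_L * I / (1 + p$alpha_I * I) - p$n_I * (I - Q) +
        u_ex / p$V_I + (1 - p$x_L) * uen / p$V_I,
      p$n_I * (I - Q) - p$n_C * Q / (1 + p$alpha_G * Q))
  }
  sol <- pracma::fsolve(f, guess, tol = 1e-12)
  stats::setNames(sol$x, c("G", "I", "Q"))
}

## Euler integration of the SI-free insulin subsystem driven by a glucose
## interpolant (function of time) and a constant exogenous rate.
oracle_euler_insulin <- function(I0, Q0, params, G_fun, u_fun, horizon,
                                 dt = 0.01, keep = horizon) {
  p <- params
  out <- matrix(NA_real_, length(keep), 2L, dimnames = list(NULL, c("I", "Q")))
  I <- I0; Q <- Q0; t <- 0; ki <- 1L
  n <- round(horizon / dt)
  for (s in seq_len(n)) {
    G <- G_fun(t)
    uen <- min(p$u_en_max, max(p$u_en_basal, p$u_en_slope * G + p$u_en_intercept))
    dI <- -p$n_K * I - p$n_L * I / (1 + p$alpha_I * I) - p$n_I * (I - Q) +
      u_fun(t) / p$V_I + (1 - p$x_L) * uen / p$V_I
    dQ <- p$n_I * (I - Q) - p$n_C * Q / (1 + p$alpha_G * Q)
    I <- I + dt * dI; Q <- Q + dt * dQ
    t <- t + dt
    while (ki <= length(keep) && t >= keep[ki] - dt / 2) {
      out[ki, ] <- c(I, Q)
      ki <- ki + 1L
    }
  }
  out
}

## Brute-force scalar-minimisation fit of one hour's SI: simulate the glucose
## equation over the hour by Euler for a candidate SI (with I, Q from the
## Euler insulin oracle and endogenous secretion on the measured-BG
## interpolant) and minimise the squared end-of-hour mismatch.
oracle_si_minimize <- function(record, params, hour, dt = 0.01) {
  p <- params
  t0 <- record$therapy_start
  G_fun <- function(t) {
    stats::approx(record$bg$time - t0, record$bg$value, xout = t, rule = 2)$y
  }
  u_rate <- function(t) {
    i <- findInterval(t + t0, record$insulin$time)
    1000 / 60 * if (i < 1L) 0 else record$insulin$rate[i]
  }
  P_rate <- function(t) {
    i <- findInterval(t + t0, record$nutrition$time)
    (1000 / 180.156) / 60 * if (i < 1L) 0 else record$nutrition$rate[i]
  }
  iq0 <- steady_insulin_state(G_fun(0), 0, p)
  span <- (hour + 1L) * 60
  kp <- seq(dt, span, by = dt)
  iq <- oracle_euler_insulin(iq0[["I"]], iq0[["Q"]], p, G_fun, u_rate,
                             horizon = span, dt = dt, keep = kp)
  hidx <- kp > hour * 60 & kp <= span
  Qh <- iq[hidx, "Q"]
  g_start <- G_fun(hour * 60)
  g_end <- G_fun(span)
  loss <- function(si) {
    G <- g_start
    tt <- hour * 60
    for (q in Qh) {
      dG <- -p$p_G * G - si * G * q / (1 + p$alpha_G * q) +
        (P_rate(tt) + p$EGP - p$CNS) / p$V_G
      G <- G + dt * dG
      tt <- tt + dt
    }
    (G - g_end)^2
  }
  stats::optimize(loss, c(0, 5e-3), tol = 1e-12)$minimum
}

## Noise-free record generated directly from the forward model (independent of
## the cohort generator): constant insulin/feed, BG sampled every
## `sample_dt` minutes.
make_simulated_record <- function(params, si_vals, hours, insulin_u_h = 3,
                                  feed_g_h = 6, G0 = 8, sample_dt = 5,
                                  patient_id = "sim") {
  iq0 <- steady_insulin_state(G0, 0, params)
  init <- model_state(G = G0, I = iq0[["I"]], Q = iq0[["Q"]])
  sched <- input_schedule(0, u_ex = insulin_u_per_h_to_mu_per_min(insulin_u_h),
                          P = carb_g_per_h_to_mmol_per_min(feed_g_h))
  tr <- simulate_icing(init, params, si_trajectory(si_vals), sched,
                       horizon = hours * 60, output_dt = sample_dt)
  patient_record(patient_id, "survivor",
                 bg = data.frame(time = tr$time_min, value = tr$G),
                 insulin = data.frame(time = 0, rate = insulin_u_h),
                 nutrition = data.frame(time = 0, rate = feed_g_h))
}

## Cached small cohorts shared across test files (generation is the expensive
## step; assertions are cheap).
.cohort_cache <- new.env(parent = emptyenv())
get_test_cohort <- function(key, config) {
  if (!exists(key, envir = .cohort_cache)) {
    assign(key, generate_cohort(config, default_icing_params()),
           envir = .cohort_cache)
  }
  get(key, envir = .cohort_cache)
}
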