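params <- default_icing_params()

test_that("BG interpolation is linear, exact at measurements, and matches the two-point formula", {
  bg <- data.frame(time = c(0, 60), value = c(5, 7))
  expect_equal(interpolate_bg(bg, 30), 6)
  expect_equal(interpolate_bg(bg, c(0, 60)), c(5, 7))
  set.seed(42)
  bg2 <- data.frame(time = sort(sample(0:600, 12)),
                    value = runif(12, 4, 10))
  grid <- seq(min(bg2$time), max(bg2$time), by = 0.5)
  byhand <- vapply(grid, function(t) {
    i <- max(which(bg2$time <= t))
    if (i == nrow(bg2)) return(bg2$value[i])
    w <- (t - bg2$time[i]) / (bg2$time[i + 1] - bg2$time[i])
    (1 - w) * bg2$value[i] + w * bg2$value[i + 1]
  }, numeric(1))
  expect_equal(interpolate_bg(bg2, grid), byhand)
  expect_error(interpolate_bg(bg2, -5), "span")
})

test_that("insulin compartments are zero without insulin and track oracles otherwise", {
  p0 <- default_icing_params(u_en_basal = 0, u_en_max = 0)
  rec0 <- patient_record("z", "survivor",
                         bg = data.frame(time = seq(0, 240, 60),
                                         value = rep(6, 5)),
                         insulin = data.frame(time = 0, rate = 0),
                         nutrition = data.frame(time = 0, rate = 4))
  iq <- simulate_insulin_compartments(rec0, p0)
  expect_identical(max(abs(iq$I)), 0)
  expect_identical(max(abs(iq$Q)), 0)

  ## long-horizon convergence to the root-found two-equation equilibrium
  p_lin <- default_icing_params(alpha_I = 0, u_en_basal = 0, u_en_max = 0)
  u_mu <- 50
  rec1 <- patient_record("c", "survivor",
                         bg = data.frame(time = seq(0, 1800, 60),
                                         value = rep(6, 31)),
                         insulin = data.frame(time = 0, rate = u_mu * 60 / 1000),
                         nutrition = data.frame(time = 0, rate = 4))
  iq1 <- simulate_insulin_compartments(rec1, p_lin)
  ## independent equilibrium: solve dQ = 0 for I(Q), then dI = 0 by uniroot
  f <- function(Q) {
    I <- Q + (p_lin$n_C / p_lin$n_I) * Q / (1 + p_lin$alpha_G * Q)
    -p_lin$n_K * I - p_lin$n_L * I - p_lin$n_I * (I - Q) + u_mu / p_lin$V_I
  }
  Qs <- uniroot(f, c(0, 1e4), tol = 1e-12)$root
  Is <- Qs + (p_lin$n_C / p_lin$n_I) * Qs / (1 + p_lin$alpha_G * Qs)
  expect_lt(abs(iq1$I[nrow(iq1)] - Is) / Is, 1e-3)
  expect_lt(abs(iq1$Q[nrow(iq1)] - Qs) / Qs, 1e-3)

  ## agreement with the fine-step Euler oracle under time-varying BG
  bg <- data.frame(time = seq(0, 240, by = 30),
                   value = c(9, 8.2, 7.1, 6.4, 6.0, 5.8, 5.9, 6.1, 6.0))
  rec2 <- patient_record("e", "survivor", bg = bg,
                         insulin = data.frame(time = c(0, 120), rate = c(2, 4)),
                         nutrition = data.frame(time = 0, rate = 5))
  iq2 <- simulate_insulin_compartments(rec2, params)
  G_fun <- function(t) approx(bg$time, bg$value, xout = t, rule = 2)$y
  u_fun <- function(t) if (t < 120) 2000 / 60 else 4000 / 60
  iq0 <- steady_insulin_state(9, 0, params)
  keep <- seq(60, 240, by = 60)
  orc <- oracle_euler_insulin(iq0[["I"]], iq0[["Q"]], params, G_fun, u_fun,
                              horizon = 240, dt = 0.01, keep = keep)
  sim <- as.matrix(iq2[match(keep, iq2$time), c("I", "Q")])
  expect_lt(max(abs(sim - orc) / orc), 1e-4)
})

test_that("the hourly integral solve recovers a known constant SI from noise-free data", {
  rec <- make_simulated_record(params, rep(3e-4, 7), hours = 6, sample_dt = 5)
  for (h in c(0, 2, 5)) {
    fit <- fit_si_hour(rec, params, h)
    expect_identical(fit$flag, "ok")
    expect_lt(abs(fit$si - 3e-4) / 3e-4, 0.005)
  }
})

test_that("zero true SI clamps at the floor and zero insulin is unidentifiable", {
  rec0 <- make_simulated_record(params, rep(0, 4), hours = 3, sample_dt = 5)
  f0 <- fit_si_hour(rec0, params, 1)
  expect_true(f0$flag == "clamped" || f0$si <= 1e-6)

  p_noins <- default_icing_params(u_en_basal = 0, u_en_max = 0)
  rec1 <- make_simulated_record(p_noins, rep(3e-4, 4), hours = 3,
                                insulin_u_h = 0, sample_dt = 10)
  f1 <- fit_si_hour(rec1, p_noins, 1)
  expect_identical(f1$flag, "unidentifiable")
  expect_true(is.na(f1$si))
})

test_that("profiles cover exactly the whole hours with BG coverage", {
  rec <- make_simulated_record(params, rep(3e-4, 73), hours = 72,
                               sample_dt = 30)
  prof <- fit_si_profile(rec, params, horizon_hours = 72)
  expect_identical(nrow(prof), 72L)
  expect_true(all(prof$flag == "ok"))

  rec30 <- make_simulated_record(params, rep(3e-4, 31), hours = 30,
                                 sample_dt = 30)
  expect_identical(nrow(fit_si_profile(rec30, params, 72)), 30L)

  expect_error(
    fit_si_profile(patient_record("few", "survivor",
                                  bg = data.frame(time = 0, value = 6),
                                  insulin = data.frame(time = 0, rate = 1),
                                  nutrition = data.frame(time = 0, rate = 4)),
                   params),
    ">= 2 BG")
})

test_that("a stepping daily SI profile is recovered hour by hour", {
  si_days <- c(rep(2e-4, 24), rep(4e-4, 24), rep(3e-4, 25))
  rec <- make_simulated_record(params, si_days, hours = 72, sample_dt = 5)
  prof <- fit_si_profile(rec, params, 72)
  err <- abs(prof$si - si_days[prof$hour + 1]) / si_days[prof$hour + 1]
  expect_lt(max(err), 0.02)
})

test_that("identification is deterministic", {
  rec <- make_simulated_record(params, c(2e-4, 3e-4, 2.5e-4, 2.5e-4),
                               hours = 3, sample_dt = 15)
  expect_identical(fit_si_profile(rec, params, 3),
                   fit_si_profile(rec, params, 3))
})

test_that("raising all BG by a common factor never increases identified SI", {
  rec <- make_simulated_record(params, rep(3e-4, 5), hours = 4, sample_dt = 10)
  fits <- lapply(c(1, 1.05, 1.2, 1.5), function(cc) {
    r <- rec
    r$bg$value <- r$bg$value * cc
    fit_si_profile(r, params, 4)$si
  })
  for (k in 2:length(fits)) {
    expect_true(all(fits[[k]] <= fits[[k - 1]] + 1e-12))
  }
})

test_that("hourly SI is recovered across a noise-free cohort", {
  cfg <- cohort_config(n_survivors = 6, n_nonsurvivors = 6, seed = 301,
                       bg_error_sd = 0, measurement_interval = 60)
  co <- get_test_cohort("recovery_hourly", cfg)
  errs <- unlist(lapply(names(co$records), function(id) {
    prof <- fit_si_profile(co$records[[id]], params)
    tr <- co$truth[co$truth$patient_id == id, ]
    m <- merge(prof[prof$flag != "unidentifiable", ], tr, by = "hour")
    abs(m$si - m$true_si) / m$true_si
  }))
  expect_gt(length(errs), 500)
  expect_lt(median(errs), 0.05)
})

test_that("5-minute sampling brings median recovery error below 1%", {
  cfg <- cohort_config(n_survivors = 2, n_nonsurvivors = 0, seed = 302,
                       bg_error_sd = 0, measurement_interval = 5,
                       horizon_hours = 12,
                       los_distribution = list(meanlog = log(200), sdlog = 0.1,
                                               min_hours = 12))
  co <- get_test_cohort("recovery_5min", cfg)
  errs <- unlist(lapply(names(co$records), function(id) {
    prof <- fit_si_profile(co$records[[id]], params, horizon_hours = 12)
    tr <- co$truth[co$truth$patient_id == id, ]
    m <- merge(prof[prof$flag != "unidentifiable", ], tr, by = "hour")
    abs(m$si - m$true_si) / m$true_si
  }))
  expect_lt(median(errs), 0.01)
})

test_that("the identified SI responds to multiplicative BG noise without median bias", {
  cfg <- cohort_config(n_survivors = 10, n_nonsurvivors = 10, seed = 303,
                       bg_error_sd = 0, measurement_interval = 60)
  co <- get_test_cohort("noise_response", cfg)
  set.seed(991)
  rel <- unlist(lapply(names(co$records), function(id) {
    r <- co$records[[id]]
    clean <- fit_si_profile(r, params)
    z <- pmin(pmax(rnorm(nrow(r$bg)), -3), 3)
    r$bg$value <- r$bg$value * (1 + 0.094 * z)
    noisy <- fit_si_profile(r, params)
    m <- merge(noisy[noisy$flag != "unidentifiable", ],
               clean[clean$flag != "unidentifiable", ], by = "hour")
    (m$si.x - m$si.y) / m$si.y
  }))
  expect_gt(length(rel), 1000)
  expect_gt(binom.test(sum(rel > 0), length(rel))$p.value, 0.01)
})

test_that("profile CSV round-trips losslessly", {
  rec <- make_simulated_record(params, rep(3e-4, 4), hours = 3, sample_dt = 15)
  prof <- fit_si_profile(rec, params, 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_si_profiles_csv(prof, path)
  back <- read_si_profiles_csv(path)[[1]]
  expect_equal(back$si, prof$si)
  expect_identical(back$flag, prof$flag)
})
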