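params <- default_icing_params()

test_that("SI trajectories are constant when every stochastic term is off", {
  cfg <- cohort_config(delta_si_sd_start = 0, delta_si_sd_end = 0,
                       si_drift = 1, si_baseline_sd = 0, seed = 1)
  tr <- sample_si_trajectory(cfg, "survivor")
  expect_equal(tr$values, rep(cfg$si_level_median, length(tr$values)))
  trn <- sample_si_trajectory(cfg, "non-survivor")
  expect_equal(trn$values,
               rep(cfg$si_level_median * cfg$nonsurvivor_si_multiplier,
                   length(trn$values)))
})

test_that("the group multiplier shows up in the pooled median SI ratio", {
  cfg <- cohort_config(seed = 1)
  set.seed(210)
  med <- function(group) {
    median(unlist(lapply(1:200, function(i) {
      sample_si_trajectory(cfg, group)$values
    })))
  }
  ratio <- med("non-survivor") / med("survivor")
  expect_gt(ratio, 1.1)
  expect_lt(ratio, 1.3)
})

test_that("trajectories and cohorts are seed-deterministic", {
  cfg <- cohort_config(seed = 33)
  t1 <- withr::with_seed(5, sample_si_trajectory(cfg, "survivor"))
  t2 <- withr::with_seed(5, sample_si_trajectory(cfg, "survivor"))
  expect_identical(t1, t2)

  cfg_small <- cohort_config(n_survivors = 2, n_nonsurvivors = 1, seed = 33,
                             horizon_hours = 24,
                             los_distribution = list(meanlog = log(30),
                                                     sdlog = 0.3,
                                                     min_hours = 24))
  c1 <- generate_cohort(cfg_small, params)
  c2 <- generate_cohort(cfg_small, params)
  expect_identical(c1$records, c2$records)
  expect_identical(c1$truth, c2$truth)
})

test_that("the stylised protocol holds in band, saturates under hyperglycaemia, and quantises", {
  ct <- cohort_config()$controller
  hold <- stylized_controller(c(5.7, 5.5), insulin_rate = 2,
                              feed_fraction = 0.85, ct)
  expect_identical(hold$insulin_rate, 2)
  expect_identical(hold$feed_fraction, 0.85)

  u <- 0; fr <- 1
  for (k in 1:8) {
    act <- stylized_controller(rep(12, k + 1), u, fr, ct)
    u <- act$insulin_rate; fr <- act$feed_fraction
  }
  expect_identical(u, ct$max_insulin)
  expect_identical(fr, min(ct$feed_fractions))
  expect_identical(u %% ct$insulin_step, 0)

  stopd <- stylized_controller(c(5.5, 3.9), insulin_rate = 4,
                               feed_fraction = 0.5, ct)
  expect_identical(stopd$insulin_rate, 0)
  expect_gt(stopd$feed_fraction, 0.5)
})

test_that("closed-loop control keeps the cohort median BG inside the target band", {
  cfg <- cohort_config(n_survivors = 25, n_nonsurvivors = 25, seed = 502)
  co <- get_test_cohort("band50", cfg)
  allbg <- unlist(lapply(co$records, function(r) r$bg$value))
  expect_gt(median(allbg), 4.4)
  expect_lt(median(allbg), 8.0)
})

test_that("generated records satisfy the record invariants and the sampling cadence", {
  cfg <- cohort_config(n_survivors = 25, n_nonsurvivors = 25, seed = 502)
  co <- get_test_cohort("band50", cfg)
  expect_length(co$records, 50)
  expect_identical(sum(vapply(co$records, function(r)
    r$outcome == "survivor", logical(1))), 25L)
  for (r in co$records[1:10]) {
    expect_true(all(diff(r$bg$time) > 0))
    expect_true(all(r$bg$value > 0))
    expect_gte(r$therapy_start, r$admission_time)
    expect_lte(r$therapy_start - r$admission_time, 12 * 60)
    ## ~16 measurements per day at the 90-min default cadence
    first_day <- sum(r$bg$time - r$therapy_start < 24 * 60)
    expect_identical(first_day, 16L)
  }
})

test_that("dropout matches the configured length-of-stay distribution", {
  cfg <- cohort_config(n_survivors = 25, n_nonsurvivors = 25, seed = 502)
  co <- get_test_cohort("band50", cfg)
  dur <- vapply(co$records, function(r) {
    (max(r$bg$time) - r$therapy_start) / 60
  }, numeric(1))
  p72 <- 1 - plnorm(72, cfg$los_distribution$meanlog,
                    cfg$los_distribution$sdlog)
  obs <- mean(dur >= 72)
  band <- 2.9 * sqrt(p72 * (1 - p72) / 50)
  expect_gt(obs, p72 - band)
  expect_lt(obs, p72 + band)
})

test_that("with no measurement error the stored BG equals the simulated BG", {
  los24 <- list(meanlog = log(24), sdlog = 0.01, min_hours = 24)
  cfg0 <- cohort_config(bg_error_sd = 0, horizon_hours = 24,
                        los_distribution = los24)
  pt0 <- withr::with_seed(61, generate_patient(cfg0, "survivor", params, "x"))
  expect_identical(pt0$record$bg$value, pt0$truth$bg_true$value)

  cfg9 <- cohort_config(bg_error_sd = 9.4, horizon_hours = 24,
                        los_distribution = los24)
  pt9 <- withr::with_seed(61, generate_patient(cfg9, "survivor", params, "x"))
  expect_false(isTRUE(all.equal(pt9$record$bg$value,
                                pt9$truth$bg_true$value)))
})

test_that("a noise-free generated record round-trips through identification", {
  cfg <- cohort_config(n_survivors = 3, n_nonsurvivors = 0, seed = 62,
                       bg_error_sd = 0, measurement_interval = 60,
                       horizon_hours = 36,
                       los_distribution = list(meanlog = log(48), sdlog = 0.1,
                                               min_hours = 36))
  co <- generate_cohort(cfg, params)
  errs <- unlist(lapply(names(co$records), function(id) {
    prof <- fit_si_profile(co$records[[id]], params, horizon_hours = 36)
    m <- merge(prof[prof$flag != "unidentifiable", ],
               co$truth[co$truth$patient_id == id, ], by = "hour")
    abs(m$si - m$true_si) / m$true_si
  }))
  expect_lt(median(errs), 0.05)
})

test_that("cohort CSV artefacts round-trip", {
  cfg <- cohort_config(n_survivors = 2, n_nonsurvivors = 1, seed = 63,
                       horizon_hours = 24,
                       los_distribution = list(meanlog = log(30), sdlog = 0.2,
                                               min_hours = 24))
  co <- generate_cohort(cfg, params)
  dir <- withr::local_tempdir()
  paths <- write_cohort_csv(co, dir)
  back <- read_patient_records(paths[1], paths[2])
  expect_identical(names(back), names(co$records))
  expect_equal(back[[1]]$bg$value, co$records[[1]]$bg$value)
  expect_identical(back[[1]]$outcome, co$records[[1]]$outcome)

  cfg_path <- file.path(dir, "config.yaml")
  write_cohort_config(cfg, cfg_path)
  cfg_back <- read_cohort_config(cfg_path)
  expect_equal(unclass(cfg_back), unclass(cfg))
})
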