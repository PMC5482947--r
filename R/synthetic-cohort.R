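## Virtual-patient cohort generator: lognormal, mean-reverting hourly SI
## dynamics with a group-level offset, a stylised insulin-nutrition feedback
## protocol, multiplicative BG measurement error and length-of-stay dropout.
## The generator emulates the statistical structure the analysis assumes; it
## is an emulation, not a fit to any clinical data set.

#' Configuration of the synthetic cohort generator
#'
#' @param n_survivors,n_nonsurvivors group sizes
#' @param si_level_median survivor-group median SI at therapy start (L/mU/min)
#' @param nonsurvivor_si_multiplier multiplicative offset of the non-survivor
#'   group's median SI (e.g. 1.2 = 20% higher)
#' @param si_baseline_sd between-patient SD of log SI at therapy start
#' @param si_mean_reversion hourly autoregressive coefficient of log SI about
#'   the drifting group median (1 = pure random walk; < 1 mean-reverting, so
#'   between-patient dispersion narrows over time as in stabilising cohorts)
#' @param delta_si_sd_start,delta_si_sd_end SD of the multiplicative
#'   hour-to-hour SI step (percent, log scale x 100) at hour 0 and at hour 72;
#'   linearly interpolated between (variability decreases over the stay)
#' @param si_drift deterministic daily upward drift factor of the group median
#'   SI (recovery trend)
#' @param bg_error_sd multiplicative BG measurement error SD (percent),
#'   truncated at +/- 3 SD
#' @param measurement_interval BG measurement spacing (min)
#' @param los_distribution lognormal therapy-duration sampler:
#'   list(meanlog, sdlog, min_hours) (hours)
#' @param controller stylised glycaemic-control protocol parameters: list
#'   with `target_lo`, `target_hi` (mmol/L band), `max_insulin` (U/h cap),
#'   `insulin_step` (U/h quantum), `goal_feed` (g/h), `feed_fractions`
#'   (allowed fractions of goal feed), `hyper_threshold` (sustained-hyper
#'   feed-cut trigger, mmol/L), `upper_trigger` (upper-band level above which
#'   rising BG already earns an insulin step, mmol/L), `fall_threshold`
#'   (in-band fast-fall insulin back-off, mmol/L per interval)
#' @param initial_bg lognormal initial-BG sampler: list(meanlog, sdlog, min,
#'   max) (mmol/L)
#' @param horizon_hours simulated therapy horizon (h); records are truncated
#'   at the sampled length of stay
#' @param seed integer seed controlling all generator randomness
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_survivors = 119, n_nonsurvivors = 26,
                          si_level_median = 1.5e-4,
                          nonsurvivor_si_multiplier = 1.2,
                          si_baseline_sd = 0.9,
                          si_mean_reversion = 0.95,
                          delta_si_sd_start = 40, delta_si_sd_end = 8,
                          si_drift = 1.35,
                          bg_error_sd = 9.4, measurement_interval = 90,
                          los_distribution = list(meanlog = log(80),
                                                  sdlog = 1.0,
                                                  min_hours = 12),
                          controller = list(target_lo = 4.4, target_hi = 8.0,
                                            max_insulin = 6, insulin_step = 1,
                                            goal_feed = 6,
                                            feed_fractions = c(0.3, 0.5, 0.7,
                                                               0.85, 1),
                                            hyper_threshold = 8.5,
                                            upper_trigger = 6.5,
                                            fall_threshold = 1.5),
                          initial_bg = list(meanlog = log(9), sdlog = 0.2,
                                            min = 5, max = 15),
                          horizon_hours = 78, seed = 1) {
  cfg <- list(n_survivors = n_survivors, n_nonsurvivors = n_nonsurvivors,
              si_level_median = si_level_median,
              nonsurvivor_si_multiplier = nonsurvivor_si_multiplier,
              si_baseline_sd = si_baseline_sd,
              si_mean_reversion = si_mean_reversion,
              delta_si_sd_start = delta_si_sd_start,
              delta_si_sd_end = delta_si_sd_end,
              si_drift = si_drift, bg_error_sd = bg_error_sd,
              measurement_interval = measurement_interval,
              los_distribution = los_distribution, controller = controller,
              initial_bg = initial_bg, horizon_hours = horizon_hours,
              seed = seed)
  stopifnot(cfg$n_survivors >= 0, cfg$n_nonsurvivors >= 0,
            cfg$si_level_median > 0, cfg$nonsurvivor_si_multiplier > 0,
            cfg$si_baseline_sd >= 0, cfg$si_mean_reversion > 0,
            cfg$si_mean_reversion <= 1, cfg$delta_si_sd_start >= 0,
            cfg$delta_si_sd_end >= 0, cfg$si_drift > 0, cfg$bg_error_sd >= 0,
            cfg$measurement_interval > 0, cfg$horizon_hours >= 1)
  class(cfg) <- "cohort_config"
  cfg
}

#' Read/write a cohort configuration (YAML or JSON)
#'
#' @param path file path (`.yaml`/`.yml`/`.json`)
#' @return [read_cohort_config()]: a `cohort_config`;
#'   [write_cohort_config()]: `path`, invisibly.
#' @export
read_cohort_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    yml = ,
    yaml = yaml::read_yaml(path),
    .stopf("unsupported config extension '%s'", ext)
  )
  do.call(cohort_config, raw)
}

#' @rdname read_cohort_config
#' @param config a `cohort_config`
#' @export
write_cohort_config <- function(config, path) {
  ext <- tolower(tools::file_ext(path))
  x <- unclass(config)
  if (ext == "json") {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

#' Sample one "true" hourly SI trajectory
#'
#' Log SI follows a mean-reverting multiplicative walk about the group's
#' drifting median: `log SI_h = mu_h + a_h` with
#' `a_{h+1} = phi * a_h + sigma_h * eps`, `a_0 ~ N(0, si_baseline_sd^2)`,
#' where `mu_h` drifts upward by `si_drift` per day (scaled by the
#' non-survivor multiplier for that group) and `sigma_h` interpolates the
#' configured hour-to-hour SDs. Values are truncated to
#' `[1e-6, 5e-3]` L/mU/min. Uses the current RNG stream.
#'
#' @param config a [cohort_config()]
#' @param group `"survivor"` or `"non-survivor"`
#' @param n_hours trajectory length (defaults to `horizon_hours + 1`)
#' @return An [si_trajectory()].
#' @export
sample_si_trajectory <- function(config, group = c("survivor", "non-survivor"),
                                 n_hours = NULL) {
  group <- match.arg(group)
  if (is.null(n_hours)) n_hours <- config$horizon_hours + 1L
  mult <- if (group == "non-survivor") config$nonsurvivor_si_multiplier else 1
  h <- 0:(n_hours - 1L)
  mu <- log(config$si_level_median * mult) + log(config$si_drift) * h / 24
  sigma <- (config$delta_si_sd_start +
              (config$delta_si_sd_end - config$delta_si_sd_start) *
                pmin(h, 72) / 72) / 100
  a <- numeric(n_hours)
  a[1L] <- stats::rnorm(1L, 0, config$si_baseline_sd)
  phi <- config$si_mean_reversion
  if (n_hours > 1L) {
    eps <- stats::rnorm(n_hours - 1L)
    for (k in seq_len(n_hours - 1L)) {
      a[k + 1L] <- phi * a[k] + sigma[k] * eps[k]
    }
  }
  si_trajectory(.clamp(exp(mu + a), 1e-6, 5e-3), start_hour = 0L)
}

#' Stylised glycaemic-control protocol step
#'
#' A deterministic, quantised insulin-and-nutrition feedback rule standing in
#' for table-based ICU protocols: insulin rises stepwise above the target band
#' (faster when BG is also rising) up to a cap, backs off on fast in-band
#' falls, stops below the band; feed is stepped down through the allowed
#' fractions under sustained hyperglycaemia and stepped back up below the
#' band.
#'
#' @param bg_history numeric vector of measured BG so far (mmol/L), most
#'   recent last; at least one value
#' @param insulin_rate current insulin rate (U/h)
#' @param feed_fraction current fraction of goal feed
#' @param controller the `controller` list of a [cohort_config()]
#' @return list with `insulin_rate` (U/h), `feed_fraction`, and `feed_rate`
#'   (g/h) for the next interval.
#' @export
stylized_controller <- function(bg_history, insulin_rate, feed_fraction,
                                controller) {
  if (!length(bg_history)) .stopf("controller needs at least one BG value")
  ct <- controller
  bg <- bg_history[length(bg_history)]
  prev <- if (length(bg_history) >= 2L) bg_history[length(bg_history) - 1L] else bg
  fr <- sort(ct$feed_fractions)
  fi <- which.min(abs(fr - feed_fraction))
  u <- insulin_rate
  if (bg < ct$target_lo) {
    u <- 0
    fi <- min(fi + 1L, length(fr))
  } else if (bg <= ct$target_hi) {
    if (prev - bg > ct$fall_threshold) {
      u <- max(0, u - ct$insulin_step)
    } else if (bg > ct$upper_trigger && bg > prev + 0.3) {
      u <- min(ct$max_insulin, u + ct$insulin_step)
    }
  } else {
    inc <- ct$insulin_step * (1L + (bg > prev))
    u <- min(ct$max_insulin, u + inc)
    if (bg > ct$hyper_threshold && prev > ct$hyper_threshold) {
      fi <- max(fi - 1L, 1L)
    }
  }
  u <- round(u / ct$insulin_step) * ct$insulin_step
  list(insulin_rate = u, feed_fraction = fr[fi],
       feed_rate = fr[fi] * ct$goal_feed)
}

## Integrate the full model over [t0, t1] (therapy-relative minutes) under
## constant inputs, restarting at every hour boundary so the hourly SI steps
## are honoured exactly.
.simulate_span <- function(y, params, si_values, u_ex, P, t0, t1) {
  lo <- ceiling(t0 / 60); hi <- floor(t1 / 60)
  hours <- if (hi >= lo) (lo:hi) * 60 else numeric(0)
  breaks <- sort(unique(c(t0, hours[hours > t0 & hours < t1], t1)))
  deriv <- function(t, y, parms) {
    list(.icing_deriv(y, params, parms$si, parms$u_ex, parms$P))
  }
  for (k in seq_len(length(breaks) - 1L)) {
    a <- breaks[k]; b <- breaks[k + 1L]
    si <- si_values[min(length(si_values), floor((a + b) / 120) + 1L)]
    sol <- deSolve::lsoda(y, c(a, b), deriv,
                          list(si = si, u_ex = u_ex, P = P),
                          rtol = 1e-6, atol = 1e-8)
    if (attr(sol, "istate")[1L] < 0 || any(!is.finite(sol[2L, -1L]))) {
      .stopf("cohort simulation failed near t = %g min", a)
    }
    y <- pmax(sol[2L, c("G", "I", "Q")], 0)
  }
  y
}

#' Generate one virtual patient
#'
#' Runs the glucose-insulin model in closed loop with the stylised protocol
#' under a sampled "true" SI trajectory: BG is measured every
#' `measurement_interval` minutes with multiplicative Gaussian error
#' (truncated at 3 SD), the controller sets the insulin and feed rates for the
#' next interval, and the record is truncated at the sampled therapy duration.
#' Therapy starts uniformly within 12 h of admission (admission is t = 0).
#' Uses the current RNG stream; seed via [generate_cohort()] or
#' [`.with_seed`]-style wrappers.
#'
#' @param config a [cohort_config()]
#' @param group `"survivor"` or `"non-survivor"`
#' @param params an [icing_params()] object
#' @param patient_id identifier for the record
#' @return list with `record` (a [patient_record()]) and `truth` (list with
#'   `si`: data.frame `hour`, `true_si`; `bg_true`: data.frame `time`,
#'   `value` of noise-free BG at the sample times).
#' @export
generate_patient <- function(config, group = c("survivor", "non-survivor"),
                             params = default_icing_params(),
                             patient_id = "P001") {
  group <- match.arg(group)
  ct <- config$controller
  therapy_start <- round(stats::runif(1L, 0, 12 * 60))
  los <- config$los_distribution
  los_hours <- max(los$min_hours,
                   stats::rlnorm(1L, los$meanlog, los$sdlog))
  sim_hours <- min(config$horizon_hours, los_hours)
  ib <- config$initial_bg
  G0 <- .clamp(stats::rlnorm(1L, ib$meanlog, ib$sdlog), ib$min, ib$max)
  si_true <- sample_si_trajectory(config, group)

  t_meas <- seq(0, floor(sim_hours * 60), by = config$measurement_interval)
  n_meas <- length(t_meas)
  iq0 <- steady_insulin_state(G0, 0, params)
  y <- c(G = G0, I = iq0[["I"]], Q = iq0[["Q"]])

  bg_true <- numeric(n_meas); bg_meas <- numeric(n_meas)
  ins_rate <- numeric(n_meas); feed_rate <- numeric(n_meas)
  u <- 0; frac <- 1
  err_sd <- config$bg_error_sd / 100
  for (k in seq_len(n_meas)) {
    bg_true[k] <- y[["G"]]
    z <- if (err_sd > 0) .clamp(stats::rnorm(1L), -3, 3) else 0
    bg_meas[k] <- max(0.5, bg_true[k] * (1 + err_sd * z))
    act <- stylized_controller(bg_meas[seq_len(k)], u, frac, ct)
    u <- act$insulin_rate; frac <- act$feed_fraction
    ins_rate[k] <- u; feed_rate[k] <- act$feed_rate
    if (k < n_meas) {
      y <- .simulate_span(y, params, si_true$values,
                          u_ex = insulin_u_per_h_to_mu_per_min(u),
                          P = carb_g_per_h_to_mmol_per_min(act$feed_rate),
                          t0 = t_meas[k], t1 = t_meas[k + 1L])
    }
  }
  keep_change <- c(TRUE, diff(ins_rate) != 0)
  keep_feed <- c(TRUE, diff(feed_rate) != 0)
  record <- patient_record(
    patient_id = patient_id, outcome = group,
    bg = data.frame(time = therapy_start + t_meas, value = bg_meas),
    insulin = data.frame(time = therapy_start + t_meas[keep_change],
                         rate = ins_rate[keep_change]),
    nutrition = data.frame(time = therapy_start + t_meas[keep_feed],
                           rate = feed_rate[keep_feed]),
    admission_time = 0, therapy_start = therapy_start
  )
  n_true_hours <- floor(sim_hours)
  truth_si <- data.frame(hour = 0:(n_true_hours - 1L),
                         true_si = si_true$values[seq_len(n_true_hours)])
  list(record = record,
       truth = list(si = truth_si,
                    bg_true = data.frame(time = therapy_start + t_meas,
                                         value = bg_true)))
}

#' Generate a reproducible virtual cohort
#'
#' @param config a [cohort_config()]; `config$seed` controls all randomness
#' @param params an [icing_params()] object
#' @return An object of class `synthetic_cohort`: list with `records` (named
#'   list of [patient_record()]), `truth` (data.frame `patient_id`, `group`,
#'   `hour`, `true_si`), and `config`.
#' @export
generate_cohort <- function(config, params = default_icing_params()) {
  groups <- c(rep("survivor", config$n_survivors),
              rep("non-survivor", config$n_nonsurvivors))
  ids <- c(sprintf("S%03d", seq_len(config$n_survivors)),
           sprintf("N%03d", seq_len(config$n_nonsurvivors)))
  out <- .with_seed(config$seed, {
    lapply(seq_along(ids), function(i) {
      generate_patient(config, groups[i], params, ids[i])
    })
  })
  records <- lapply(out, function(x) x$record)
  names(records) <- ids
  truth <- do.call(rbind, lapply(seq_along(out), function(i) {
    cbind(patient_id = ids[i], group = groups[i], out[[i]]$truth$si)
  }))
  structure(list(records = records, truth = truth, config = config),
            class = "synthetic_cohort")
}

#' Write a synthetic cohort to CSV files
#'
#' Writes the records in the long-format record dialect plus a truth table
#' (`patient_id`, `hour`, `true_si`).
#'
#' @param cohort a `synthetic_cohort`
#' @param dir output directory (created if needed)
#' @return Invisibly, the written paths.
#' @export
write_cohort_csv <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(file.path(dir, "cohort_signals.csv"),
             file.path(dir, "cohort_meta.csv"),
             file.path(dir, "cohort_truth.csv"))
  write_patient_records(cohort$records, paths[1L], paths[2L])
  utils::write.csv(cohort$truth[, c("patient_id", "hour", "true_si")],
                   paths[3L], row.names = FALSE)
  invisible(paths)
}
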