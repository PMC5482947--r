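## Difference testing (bootstrap difference of medians, KS, Bonferroni) and
## clinical equivalence testing against a measurement-error-derived range.

.fast_median <- function(v) {
  n <- length(v)
  h <- (n + 1L) %/% 2L
  if (n %% 2L == 1L) {
    sort.int(v, partial = h)[h]
  } else {
    s <- sort.int(v, partial = c(h, h + 1L))
    (s[h] + s[h + 1L]) / 2
  }
}

#' Bootstrap confidence intervals for a difference of medians
#'
#' Resamples each group with replacement at its original size `n_boot` times
#' and forms percentile intervals at 95% and 99.6% (the latter consistent with
#' a Bonferroni-corrected p = 0.004) for the difference of medians, either in
#' the metric's units (`mode = "absolute"`) or as a percentage of the second
#' group's median (`mode = "percent"`:
#' `100 * (median(x*) - median(y*)) / median(y*)`).
#'
#' @param x,y numeric samples (each `n >= 2`)
#' @param n_boot number of bootstrap resamples
#' @param seed integer seed for deterministic resampling (the caller's RNG
#'   stream is left untouched); `NULL` uses the current stream
#' @param mode `"absolute"` or `"percent"`
#' @return An object of class `bootstrap_ci`: list with `point`, `ci95`,
#'   `ci996`, `n_boot`, `seed`, `mode`.
#' @export
bootstrap_median_diff <- function(x, y, n_boot = 1000, seed = NULL,
                                  mode = c("absolute", "percent")) {
  mode <- match.arg(mode)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 2L || length(y) < 2L) .stopf("each sample needs n >= 2")
  if (any(!is.finite(x)) || any(!is.finite(y))) .stopf("samples must be finite")
  my <- .fast_median(y)
  if (mode == "percent" && my == 0) {
    .stopf("percent mode undefined: median(y) is zero")
  }
  stat <- function(mx, my) {
    if (mode == "absolute") mx - my else 100 * (mx - my) / my
  }
  boots <- .with_seed(seed, {
    nx <- length(x); ny <- length(y)
    vapply(seq_len(n_boot), function(b) {
      mx <- .fast_median(x[sample.int(nx, nx, replace = TRUE)])
      myb <- .fast_median(y[sample.int(ny, ny, replace = TRUE)])
      if (mode == "percent" && myb == 0) return(NA_real_)
      stat(mx, myb)
    }, numeric(1))
  })
  boots <- boots[is.finite(boots)]
  if (!length(boots)) .stopf("all bootstrap replicates degenerate")
  structure(list(
    point = stat(.fast_median(x), my),
    ci95 = unname(stats::quantile(boots, c(0.025, 0.975))),
    ci996 = unname(stats::quantile(boots, c(0.002, 0.998))),
    n_boot = n_boot, seed = seed, mode = mode
  ), class = "bootstrap_ci")
}

#' @export
print.bootstrap_ci <- function(x, ...) {
  u <- if (x$mode == "percent") "%" else ""
  cat(sprintf("difference of medians: %.4g%s  95%% CI [%.4g, %.4g]  99.6%% CI [%.4g, %.4g]\n",
              x$point, u, x$ci95[1], x$ci95[2], x$ci996[1], x$ci996[2]))
  invisible(x)
}

#' Two-sample Kolmogorov-Smirnov test p value
#'
#' Two-sided test of bias and shape difference between two distributions.
#' Delegates to [stats::ks.test]: exact for small tie-free samples, asymptotic
#' otherwise.
#'
#' @param x,y numeric samples (each `n >= 2`)
#' @param exact passed to [stats::ks.test] (`NULL` = automatic)
#' @return p value.
#' @export
ks_two_sample <- function(x, y, exact = NULL) {
  if (length(x) < 2L || length(y) < 2L) .stopf("each sample needs n >= 2")
  suppressWarnings(stats::ks.test(x, y, exact = exact)$p.value)
}

#' Bonferroni-corrected per-test significance level
#'
#' @param alpha family-wise significance level
#' @param m number of comparisons in the family (`>= 1`)
#' @return `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m) {
  if (!.is_number(m) || m < 1) .stopf("m must be >= 1")
  alpha / m
}

#' Synthetic steady reference record for equivalence-range derivation
#'
#' A record whose BG is constant at `bg` (measured hourly) under constant
#' insulin and feed: the operating point at which the sensitivity of the
#' hourly SI solve to BG measurement error is evaluated.
#'
#' @param bg blood glucose level (mmol/L)
#' @param insulin_rate constant insulin rate (U/h)
#' @param feed_rate constant carbohydrate rate (g/h)
#' @param hours record length (h)
#' @return a [patient_record()] (synthetic).
#' @export
reference_steady_record <- function(bg, insulin_rate = 3, feed_rate = 6,
                                    hours = 4) {
  times <- seq(0, hours * 60, by = 60)
  patient_record(
    patient_id = sprintf("reference_bg%.3g", bg), outcome = "survivor",
    bg = data.frame(time = times, value = rep(bg, length(times))),
    insulin = data.frame(time = 0, rate = insulin_rate),
    nutrition = data.frame(time = 0, rate = feed_rate)
  )
}

## Hourly fit with the solve internals exposed (denominator integral and the
## insulin-mediated numerator), needed by the equivalence-range derivation.
.fit_hour_detail <- function(record, params, hour, si_min = 1e-8,
                             denom_eps = 1e-2) {
  ctx <- .si_fit_context(record, params, horizon_hours = hour + 1L)
  if (!(hour %in% ctx$hours)) {
    .stopf("reference record does not cover hour %d", hour)
  }
  i0 <- (hour - ctx$h_first) * 60 + 1L
  idx <- i0:(i0 + 60L)
  tt <- ctx$grid[idx]; G <- ctx$G[idx]; Q <- ctx$Q[idx]
  Qeff <- Q / (1 + params$alpha_G * Q)
  denom <- .trapz(tt, G * Qeff)
  dG <- G[length(G)] - G[1L]
  int_G <- .trapz(tt, G)
  appearance <- (.integrate_schedule_P(ctx$sched, tt[1L], tt[length(tt)]) +
                   (params$EGP - params$CNS) * 60) / params$V_G
  numer <- -dG - params$p_G * int_G + appearance
  list(si = numer / denom, denom = denom, numerator = numer,
       G_start = G[1L], G_end = G[length(G)])
}

#' Derive the measurement-error equivalence range
#'
#' Computes the smallest relative change in hourly identified SI that exceeds
#' blood-glucose measurement error, which defines the half-width of the
#' clinical-equivalence range. A sustained relative SI change `h` over one
#' hour shifts the hour's glucose balance by `h * SI * int(G*Q/(1+alpha_G*Q))`
#' mmol/L; equating this to the 1-SD measurement error `(bg_error_sd/100) * G`
#' and solving for `h` gives the default (`method = "threshold"`) half-width
#' `100 * (bg_error_sd/100) * G / numerator`, where the numerator of the
#' hourly integral solve is evaluated by running the identification on a
#' self-consistent steady reference record. The range depends on BG: it is
#' evaluated across `bg_grid` and reported at `reference_bg`.
#' `method = "perturb"` instead perturbs each hour-boundary BG measurement of
#' the reference record by `±bg_error_sd`% and re-runs the hourly fit,
#' reporting the maximal absolute percent change in identified SI (an audit
#' variant; it compounds interpolation side effects and is wider).
#'
#' @param params an [icing_params()] object
#' @param record optional [patient_record()] to use as the reference scenario
#'   (its final fully covered hour is used); by default a
#'   [reference_steady_record()] is built at each BG level
#' @param bg_error_sd blood-glucose measurement error SD (percent)
#' @param reference_bg BG level (mmol/L) at which the reported half-width is
#'   taken
#' @param bg_grid BG levels over which the range is evaluated
#' @param insulin_rate,feed_rate reference operating point (U/h, g/h)
#' @param method `"threshold"` (default) or `"perturb"`
#' @return An object of class `equivalence_range`: list with `half_width`
#'   (percent), `basis` (the BG error SD used), `reference_bg`, `by_bg`
#'   (data.frame of `bg`, `half_width`), `method`.
#' @export
derive_equivalence_range <- function(params, record = NULL, bg_error_sd = 9.4,
                                     reference_bg = 6,
                                     bg_grid = seq(4, 8, by = 0.5),
                                     insulin_rate = 3, feed_rate = 6,
                                     method = c("threshold", "perturb")) {
  method <- match.arg(method)
  if (bg_error_sd < 0) .stopf("bg_error_sd must be >= 0")
  hw_for_record <- function(rec) {
    last_hour <- max(.si_fit_context(rec, params, horizon_hours = 1e6)$hours,
                     -1L)
    if (last_hour < 0L) .stopf("reference record has no fully covered hour")
    det <- .fit_hour_detail(rec, params, last_hour)
    if (!is.finite(det$numerator) || det$numerator <= 0 ||
        !is.finite(det$si) || det$si <= 0) {
      .stopf("reference record is unidentifiable at hour %d", last_hour)
    }
    if (method == "threshold") {
      100 * (bg_error_sd / 100) * det$G_end / det$numerator
    } else {
      base <- det$si
      worst <- 0
      n_bg <- nrow(rec$bg)
      bnd <- which(abs((rec$bg$time - rec$therapy_start) / 60 -
                         round((rec$bg$time - rec$therapy_start) / 60)) < 1e-9)
      for (j in bnd) {
        for (s in c(-1, 1)) {
          pert <- rec
          pert$bg$value[j] <- pert$bg$value[j] * (1 + s * bg_error_sd / 100)
          f <- tryCatch(fit_si_hour(pert, params, last_hour),
                        error = function(e) NULL)
          if (!is.null(f) && is.finite(f$si)) {
            worst <- max(worst, 100 * abs(f$si - base) / base)
          }
        }
      }
      worst
    }
  }
  if (!is.null(record)) {
    hw <- hw_for_record(record)
    by_bg <- data.frame(bg = mean(record$bg$value), half_width = hw)
    ref_bg <- mean(record$bg$value)
  } else {
    bg_grid <- sort(unique(c(bg_grid, reference_bg)))
    hws <- vapply(bg_grid, function(g) {
      hw_for_record(reference_steady_record(g, insulin_rate, feed_rate))
    }, numeric(1))
    by_bg <- data.frame(bg = bg_grid, half_width = hws)
    hw <- hws[match(reference_bg, bg_grid)]
    ref_bg <- reference_bg
  }
  structure(list(half_width = hw, basis = bg_error_sd, reference_bg = ref_bg,
                 by_bg = by_bg, method = method),
            class = "equivalence_range")
}

#' @export
print.equivalence_range <- function(x, ...) {
  cat(sprintf("equivalence half-width: +/-%.1f%% (BG %.3g mmol/L, %.3g%% BG error, %s)\n",
              x$half_width, x$reference_bg, x$basis, x$method))
  invisible(x)
}

#' Clinical-equivalence verdict for a confidence interval
#'
#' Equivalence is accepted when the whole 95% CI of the group difference lies
#' inside the equivalence range `[-half_width, +half_width]`. Equivalence and
#' statistical difference are not mutually exclusive.
#'
#' @param ci numeric length-2 interval (for SI use the percent-difference CI;
#'   for the hour-to-hour change metric use the absolute-difference CI, whose
#'   units are already percent)
#' @param range an `equivalence_range` (or a single positive half-width)
#' @return logical.
#' @export
equivalence_verdict <- function(ci, range) {
  hw <- if (inherits(range, "equivalence_range")) range$half_width else range
  if (!.is_number(hw) || hw <= 0) .stopf("equivalence half-width must be > 0")
  isTRUE(ci[1] >= -hw && ci[2] <= hw)
}

#' Full difference-and-equivalence comparison of one group x block sample pair
#'
#' Assembles the bootstrap difference-of-medians CIs (absolute and, for SI,
#' percent-of-second-group-median), the KS p value, significance at 95% and at
#' the Bonferroni-corrected 99.6% level, and the equivalence verdict against
#' the supplied range (percent CI for `metric = "si"`; absolute CI, already in
#' percent units, for `metric = "delta_si"`).
#'
#' @param x,y numeric value vectors for the two groups (e.g. survivors and
#'   non-survivors), both non-empty with `n >= 2`
#' @param range an `equivalence_range`
#' @param metric `"si"` or `"delta_si"`
#' @param m family size for the Bonferroni correction (reported, not used in
#'   the CI levels, which are fixed at 95%/99.6%)
#' @param n_boot,seed passed to [bootstrap_median_diff()]
#' @return An object of class `comparison_verdict`.
#' @export
compare_block <- function(x, y, range, metric = c("si", "delta_si"),
                          m = 12, n_boot = 1000, seed = NULL) {
  metric <- match.arg(metric)
  abs_ci <- bootstrap_median_diff(x, y, n_boot = n_boot, seed = seed,
                                  mode = "absolute")
  pct_ci <- NULL
  if (metric == "si") {
    pct_seed <- if (is.null(seed)) NULL else .child_seed(seed, 1L)
    pct_ci <- bootstrap_median_diff(x, y, n_boot = n_boot, seed = pct_seed,
                                    mode = "percent")
  }
  sig95 <- abs_ci$ci95[1] > 0 || abs_ci$ci95[2] < 0
  sig_bonf <- abs_ci$ci996[1] > 0 || abs_ci$ci996[2] < 0
  equiv_ci <- if (metric == "si") pct_ci$ci95 else abs_ci$ci95
  structure(list(
    metric = metric,
    median_x = stats::median(x), median_y = stats::median(y),
    n_x = length(x), n_y = length(y),
    diff = abs_ci, percent_diff = pct_ci,
    ks_p = ks_two_sample(x, y),
    difference_significant_95 = sig95,
    significant_after_bonferroni = sig_bonf,
    bonferroni_alpha = bonferroni_threshold(0.05, m),
    half_width = if (inherits(range, "equivalence_range")) range$half_width else range,
    equivalent = equivalence_verdict(equiv_ci, range)
  ), class = "comparison_verdict")
}

#' @export
print.comparison_verdict <- function(x, ...) {
  cat(sprintf("%s block comparison: diff %.4g [%.4g, %.4g], KS p = %.3g, %s, %s\n",
              x$metric, x$diff$point, x$diff$ci95[1], x$diff$ci95[2], x$ks_p,
              if (x$difference_significant_95) "significant (95%)" else "not significant",
              if (x$equivalent) "equivalent" else "not equivalent"))
  invisible(x)
}
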