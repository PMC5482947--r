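## Cohort selection, end-to-end analysis and report rendering.

#' Select an analysis cohort
#'
#' Cohort 1: therapy started within 12 h of ICU admission (inclusive) and at
#' least 24 h of BG-covered therapy data. Cohort 2: additionally at least 72 h
#' of BG-covered therapy data (the competing-risk / dropout sensitivity
#' cohort), so cohort 2 is always a subset of cohort 1. Edge ties (exactly
#' 12 h, exactly 24 h, exactly 72 h) are inclusive.
#'
#' @param records named list of [patient_record()] objects
#' @param rule `"cohort1"` or `"cohort2"`
#' @return An object of class `cohort_selection`: list with `included`
#'   (character ids), `exclusions` (data.frame `patient_id`, `reason` in
#'   `late_start`, `short_therapy`, `short_stay_72h`), `rule`.
#' @export
select_cohort <- function(records, rule = c("cohort1", "cohort2")) {
  rule <- match.arg(rule)
  reasons <- vapply(records, function(r) {
    for (f in c("admission_time", "therapy_start")) {
      if (is.null(r[[f]]) || is.na(r[[f]])) {
        .stopf("patient %s: missing metadata field '%s'", r$patient_id, f)
      }
    }
    start_h <- (r$therapy_start - r$admission_time) / 60
    data_h <- if (nrow(r$bg)) (max(r$bg$time) - r$therapy_start) / 60 else 0
    if (start_h > 12) return("late_start")
    if (data_h < 24) return("short_therapy")
    if (rule == "cohort2" && data_h < 72) return("short_stay_72h")
    ""
  }, character(1))
  ids <- vapply(records, function(r) r$patient_id, character(1))
  structure(list(
    included = unname(ids[reasons == ""]),
    exclusions = data.frame(patient_id = unname(ids[reasons != ""]),
                            reason = unname(reasons[reasons != ""]),
                            stringsAsFactors = FALSE),
    rule = rule
  ), class = "cohort_selection")
}

.verdict_row <- function(block, v) {
  pct <- v$percent_diff
  data.frame(
    block = block,
    median_s = v$median_x, median_ns = v$median_y,
    n_s = v$n_x, n_ns = v$n_y,
    diff = v$diff$point,
    ci95_lo = v$diff$ci95[1], ci95_hi = v$diff$ci95[2],
    ci996_lo = v$diff$ci996[1], ci996_hi = v$diff$ci996[2],
    pct_diff = if (is.null(pct)) NA_real_ else pct$point,
    pct_ci95_lo = if (is.null(pct)) NA_real_ else pct$ci95[1],
    pct_ci95_hi = if (is.null(pct)) NA_real_ else pct$ci95[2],
    ks_p = v$ks_p,
    sig95 = v$difference_significant_95,
    sig_bonf = v$significant_after_bonferroni,
    half_width = v$half_width,
    equivalent = v$equivalent,
    stringsAsFactors = FALSE
  )
}

#' Run the full block-comparison analysis
#'
#' End to end: select the cohort(s), identify hourly SI for every included
#' patient, pool SI and its hour-to-hour percentage change into 6-h blocks by
#' outcome group, and for every block compute bootstrap difference-of-medians
#' CIs (95% and Bonferroni-consistent 99.6%), the KS p value, and the
#' clinical-equivalence verdict against a BG-measurement-error equivalence
#' range derived at each block's median BG. A whole-cohort BG equivalence
#' check (percent difference of group median BG against the raw
#' `bg_error_sd` range) is included.
#'
#' @param records named list of [patient_record()] objects
#' @param params an [icing_params()] object
#' @param n_boot bootstrap resamples per comparison
#' @param seed integer master seed; per-cohort/metric/block substreams are
#'   derived with fixed offsets
#' @param horizon_hours analysis horizon (h)
#' @param block_hours block length (h)
#' @param bg_error_sd BG measurement error SD (percent) used for the
#'   equivalence ranges
#' @param cohorts subset of `c("cohort1", "cohort2")`
#' @return An object of class `sivar_analysis`: per-cohort list with
#'   `selection`, `tables` (`si`, `delta_si` block tables), `pooled`,
#'   `bg_equivalence`, `ranges`, `notes`; plus `profiles` and call settings.
#' @export
run_analysis <- function(records, params = default_icing_params(),
                         n_boot = 1000, seed = 1, horizon_hours = 72,
                         block_hours = 6, bg_error_sd = 9.4,
                         cohorts = c("cohort1", "cohort2")) {
  stopifnot(length(records) >= 1L)
  n_blocks <- horizon_hours %/% block_hours
  profiles <- lapply(records, function(r) {
    fit_si_profile(r, params, horizon_hours = horizon_hours)
  })
  names(profiles) <- vapply(records, function(r) r$patient_id, character(1))
  outcomes <- vapply(records, function(r) r$outcome, character(1))
  names(outcomes) <- names(profiles)

  res <- list()
  for (ci in seq_along(cohorts)) {
    rule <- cohorts[ci]
    sel <- select_cohort(records, rule)
    inc <- sel$included
    notes <- character(0)
    sub_prof <- profiles[inc]
    sub_out <- outcomes[inc]
    have_both <- all(c("survivor", "non-survivor") %in% sub_out)
    if (!length(inc)) notes <- c(notes, "no patients selected")
    if (length(inc) && !have_both) {
      notes <- c(notes,
                 "one outcome group is empty: comparisons skipped")
    }
    tables <- list(si = NULL, delta_si = NULL)
    pooled <- list(si = NULL, delta_si = NULL)
    ranges <- NULL
    bg_eq <- NULL
    if (length(inc)) {
      ## per-block median BG (pooled, both groups) -> BG-dependent range
      bg_block <- lapply(0:(n_blocks - 1L), function(b) {
        vals <- unlist(lapply(records[inc], function(r) {
          rel <- (r$bg$time - r$therapy_start) / 60
          r$bg$value[rel >= b * block_hours & rel < (b + 1) * block_hours]
        }))
        if (length(vals)) stats::median(vals) else NA_real_
      })
      ranges <- lapply(seq_len(n_blocks), function(i) {
        bgm <- bg_block[[i]]
        if (!is.finite(bgm)) bgm <- 6
        derive_equivalence_range(params, bg_error_sd = bg_error_sd,
                                 reference_bg = bgm, bg_grid = bgm)
      })
    }
    if (length(inc) && have_both) {
      for (mi in 1:2) {
        metric <- c("si", "delta_si")[mi]
        pb <- pool_blocks(sub_prof, sub_out, metric = metric,
                          horizon_hours = horizon_hours,
                          block_hours = block_hours)
        pooled[[metric]] <- pb
        rows <- list()
        for (b in 0:(n_blocks - 1L)) {
          xs <- pb$values[pb$block == b & pb$group == "survivor"][[1L]]
          ys <- pb$values[pb$block == b & pb$group == "non-survivor"][[1L]]
          if (length(xs) < 2L || length(ys) < 2L) {
            notes <- c(notes, sprintf("%s block %d skipped (too few values)",
                                      metric, b))
            next
          }
          v <- compare_block(xs, ys, ranges[[b + 1L]], metric = metric,
                             m = n_blocks, n_boot = n_boot,
                             seed = .child_seed(seed, ci, mi, b))
          rows[[length(rows) + 1L]] <- .verdict_row(b, v)
        }
        tables[[metric]] <- if (length(rows)) do.call(rbind, rows) else NULL
      }
      ## whole-cohort BG equivalence (fixed raw measurement-error range)
      bg_s <- unlist(lapply(records[inc][sub_out == "survivor"], function(r) {
        rel <- (r$bg$time - r$therapy_start) / 60
        r$bg$value[rel >= 0 & rel < horizon_hours]
      }))
      bg_ns <- unlist(lapply(records[inc][sub_out == "non-survivor"], function(r) {
        rel <- (r$bg$time - r$therapy_start) / 60
        r$bg$value[rel >= 0 & rel < horizon_hours]
      }))
      bg_ci <- bootstrap_median_diff(bg_s, bg_ns, n_boot = n_boot,
                                     seed = .child_seed(seed, ci, 99L),
                                     mode = "percent")
      bg_eq <- list(percent_diff = bg_ci, half_width = bg_error_sd,
                    equivalent = equivalence_verdict(bg_ci$ci95, bg_error_sd))
    }
    demo <- NULL
    if (length(inc)) {
      demo <- do.call(rbind, lapply(records[inc], function(r) {
        data.frame(patient_id = r$patient_id, outcome = r$outcome,
                   median_bg = stats::median(r$bg$value),
                   median_insulin = stats::median(r$insulin$rate),
                   median_feed = stats::median(r$nutrition$rate),
                   therapy_hours = (max(r$bg$time) - r$therapy_start) / 60,
                   stringsAsFactors = FALSE)
      }))
      rownames(demo) <- NULL
    }
    res[[rule]] <- list(selection = sel, tables = tables, pooled = pooled,
                        ranges = ranges, bg_equivalence = bg_eq,
                        demographics = demo, notes = notes)
  }
  structure(list(cohorts = res, profiles = profiles,
                 settings = list(n_boot = n_boot, seed = seed,
                                 horizon_hours = horizon_hours,
                                 block_hours = block_hours,
                                 bg_error_sd = bg_error_sd)),
            class = "sivar_analysis")
}

#' @export
print.sivar_analysis <- function(x, ...) {
  for (rule in names(x$cohorts)) {
    co <- x$cohorts[[rule]]
    cat(sprintf("%s: %d included, %d excluded\n", rule,
                length(co$selection$included), nrow(co$selection$exclusions)))
    for (metric in c("si", "delta_si")) {
      tb <- co$tables[[metric]]
      if (is.null(tb)) next
      cat(sprintf("  %-8s equivalent %d/%d blocks, significant (95%%) %d, after Bonferroni %d\n",
                  metric, sum(tb$equivalent), nrow(tb), sum(tb$sig95),
                  sum(tb$sig_bonf)))
    }
    if (!is.null(co$bg_equivalence)) {
      cat(sprintf("  BG percent diff %.1f [%.1f, %.1f]%%: %s\n",
                  co$bg_equivalence$percent_diff$point,
                  co$bg_equivalence$percent_diff$ci95[1],
                  co$bg_equivalence$percent_diff$ci95[2],
                  if (co$bg_equivalence$equivalent) "equivalent" else "not equivalent"))
    }
    for (n in co$notes) cat("  note:", n, "\n")
  }
  invisible(x)
}

#' Render analysis results to CSV/text artefacts
#'
#' Writes, per cohort: the SI and hour-to-hour-change block tables, per-block
#' CDF coordinates, equivalence-bar data (percent/absolute difference point
#' and CI against the per-block range), the exclusion log, and a plain-text
#' summary. Re-running on the same results object reproduces the files
#' byte-identically.
#'
#' @param results a `sivar_analysis` from [run_analysis()]
#' @param dir output directory (created if needed)
#' @return Invisibly, the written file paths.
#' @export
render_report <- function(results, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  wr <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  summary_lines <- character(0)
  for (rule in names(results$cohorts)) {
    co <- results$cohorts[[rule]]
    wr(if (nrow(co$selection$exclusions)) co$selection$exclusions else
         data.frame(patient_id = character(0), reason = character(0)),
       sprintf("%s_exclusions.csv", rule))
    if (!is.null(co$demographics)) {
      wr(co$demographics, sprintf("%s_demographics.csv", rule))
    }
    summary_lines <- c(summary_lines,
                       sprintf("%s: %d included, %d excluded", rule,
                               length(co$selection$included),
                               nrow(co$selection$exclusions)))
    for (metric in c("si", "delta_si")) {
      tb <- co$tables[[metric]]
      if (!is.null(tb)) {
        wr(tb, sprintf("%s_blocks_%s.csv", rule, metric))
        summary_lines <- c(summary_lines,
                           sprintf("  %s: equivalent %d/%d blocks, sig95 %d, bonferroni %d",
                                   metric, sum(tb$equivalent), nrow(tb),
                                   sum(tb$sig95), sum(tb$sig_bonf)))
        bars <- data.frame(
          block = tb$block, metric = metric,
          point = if (metric == "si") tb$pct_diff else tb$diff,
          lo = if (metric == "si") tb$pct_ci95_lo else tb$ci95_lo,
          hi = if (metric == "si") tb$pct_ci95_hi else tb$ci95_hi,
          half_width = tb$half_width, equivalent = tb$equivalent)
        wr(bars, sprintf("%s_equivalence_bars_%s.csv", rule, metric))
      }
      pb <- co$pooled[[metric]]
      if (!is.null(pb)) {
        cdf <- do.call(rbind, lapply(seq_len(nrow(pb)), function(i) {
          if (!pb$n[i]) return(NULL)
          cc <- empirical_cdf(pb$values[[i]])$coords
          data.frame(block = pb$block[i], group = pb$group[i],
                     value = cc$value, fraction = cc$fraction)
        }))
        if (!is.null(cdf)) wr(cdf, sprintf("%s_cdf_%s.csv", rule, metric))
        wr(block_summary(pb), sprintf("%s_summary_%s.csv", rule, metric))
      }
    }
    if (!is.null(co$bg_equivalence)) {
      b <- co$bg_equivalence
      summary_lines <- c(summary_lines,
                         sprintf("  BG percent diff %.2f [%.2f, %.2f] vs +/-%.1f%%: %s",
                                 b$percent_diff$point, b$percent_diff$ci95[1],
                                 b$percent_diff$ci95[2], b$half_width,
                                 if (b$equivalent) "equivalent" else "not equivalent"))
    }
    for (n in co$notes) summary_lines <- c(summary_lines, paste("  note:", n))
  }
  sp <- file.path(dir, "summary.txt")
  writeLines(summary_lines, sp)
  paths <- c(paths, sp)
  invisible(paths)
}
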