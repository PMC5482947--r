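## The hour-to-hour variability statistic and 6-h block pooling.

#' Forward hour-to-hour percentage change in SI
#'
#' For every pair of consecutive identified hours `(i, i+1)` with usable
#' values (flag `ok` or `clamped`, and `SI_i > 0`), the forward percentage
#' change `100 * (SI_{i+1} - SI_i) / SI_i`, assigned to hour `i`. Gaps in the
#' profile simply produce no value.
#'
#' @param profile an `si_profile` from [fit_si_profile()]
#' @return data.frame with columns `patient_id`, `hour`, `delta_si`
#'   (percent), and `from_clamped` (logical: either endpoint was clamped,
#'   retained for sensitivity analysis)
#' @export
compute_delta_si <- function(profile) {
  p <- as.data.frame(profile)
  p <- p[p$flag %in% c("ok", "clamped") & is.finite(p$si), ]
  p <- p[order(p$hour), ]
  if (nrow(p) < 2L) {
    return(data.frame(patient_id = character(0), hour = integer(0),
                      delta_si = numeric(0), from_clamped = logical(0)))
  }
  i <- which(diff(p$hour) == 1L & p$si[-nrow(p)] > 0)
  data.frame(
    patient_id = p$patient_id[i],
    hour = p$hour[i],
    delta_si = 100 * (p$si[i + 1L] - p$si[i]) / p$si[i],
    from_clamped = p$flag[i] == "clamped" | p$flag[i + 1L] == "clamped",
    stringsAsFactors = FALSE
  )
}

#' Pool a cohort's hourly values into 6-h blocks by outcome group
#'
#' SI values at hour `h` fall in block `floor(h / block_hours)`; a
#' hour-to-hour change at hour `i` falls in the block containing `i` (the
#' block of its first hour). Pooling is across patients and hours, per group,
#' in deterministic `(patient_id, hour)` order.
#'
#' @param profiles named list of `si_profile` objects (names are patient ids)
#' @param outcomes named character vector mapping patient id to
#'   `"survivor"`/`"non-survivor"`
#' @param metric `"si"` (level, L/mU/min) or `"delta_si"` (percent change)
#' @param horizon_hours analysis horizon (hours); block count is
#'   `horizon_hours / block_hours`
#' @param block_hours hours per block
#' @return data.frame with one row per group x block: columns `block`,
#'   `group`, `n`, and a list-column `values`. Empty group-blocks are flagged
#'   by `n = 0` with a warning.
#' @export
pool_blocks <- function(profiles, outcomes, metric = c("si", "delta_si"),
                        horizon_hours = 72, block_hours = 6) {
  metric <- match.arg(metric)
  n_blocks <- horizon_hours %/% block_hours
  rows <- lapply(profiles, function(p) {
    if (metric == "si") {
      d <- as.data.frame(p)
      d <- d[d$flag %in% c("ok", "clamped") & is.finite(d$si), ]
      data.frame(patient_id = d$patient_id, hour = d$hour, value = d$si,
                 stringsAsFactors = FALSE)
    } else {
      d <- compute_delta_si(p)
      data.frame(patient_id = d$patient_id, hour = d$hour, value = d$delta_si,
                 stringsAsFactors = FALSE)
    }
  })
  all <- do.call(rbind, rows)
  all <- all[all$hour >= 0 & all$hour < horizon_hours, ]
  all$group <- unname(outcomes[all$patient_id])
  all$block <- all$hour %/% block_hours
  all <- all[order(all$patient_id, all$hour), ]
  out <- expand.grid(block = 0:(n_blocks - 1L),
                     group = c("survivor", "non-survivor"),
                     stringsAsFactors = FALSE)
  out$values <- lapply(seq_len(nrow(out)), function(i) {
    all$value[all$block == out$block[i] & all$group == out$group[i]]
  })
  out$n <- vapply(out$values, length, integer(1))
  empty <- out$n == 0L
  if (any(empty)) {
    warning(sprintf("empty group-block(s): %s",
                    paste(sprintf("%s/block %d", out$group[empty],
                                  out$block[empty]), collapse = ", ")),
            call. = FALSE)
  }
  out
}

#' Empirical cumulative distribution function of a block sample
#'
#' Right-continuous step CDF of the pooled values (the integral of the
#' empirical density), with `CDF(max) = 1`.
#'
#' @param values numeric vector of pooled values (`n >= 1`)
#' @return list with `fun` (a [stats::ecdf] step function) and `coords`
#'   (data.frame of sorted unique `value` and cumulative `fraction`), class
#'   `block_cdf`.
#' @export
empirical_cdf <- function(values) {
  values <- values[is.finite(values)]
  if (!length(values)) .stopf("empirical_cdf: empty sample")
  f <- stats::ecdf(values)
  x <- sort(unique(values))
  structure(list(fun = f, coords = data.frame(value = x, fraction = f(x))),
            class = "block_cdf")
}

#' Block summary table (medians and IQRs)
#'
#' @param pooled data.frame from [pool_blocks()]
#' @return data.frame with columns `block`, `group`, `median`, `q25`, `q75`,
#'   `n`.
#' @export
block_summary <- function(pooled) {
  qs <- t(vapply(pooled$values, function(v) {
    if (!length(v)) return(c(NA_real_, NA_real_, NA_real_))
    stats::quantile(v, c(0.5, 0.25, 0.75), names = FALSE)
  }, numeric(3)))
  data.frame(block = pooled$block, group = pooled$group,
             median = qs[, 1L], q25 = qs[, 2L], q75 = qs[, 3L],
             n = pooled$n, stringsAsFactors = FALSE)
}
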