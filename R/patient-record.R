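## Clinical-style per-patient records: blood glucose measurements plus
## piecewise-constant insulin and nutrition rates, with outcome metadata.
## Record-level units are clinical (BG mmol/L, insulin U/h, feed g/h);
## conversion to model units happens in record_schedule().

#' Per-patient clinical record
#'
#' @param patient_id opaque identifier string
#' @param outcome `"survivor"` or `"non-survivor"`
#' @param bg data.frame with columns `time` (min, strictly increasing) and
#'   `value` (mmol/L, > 0): blood glucose measurements
#' @param insulin data.frame with columns `time` (min) and `rate` (U/h):
#'   piecewise-constant bolus-equivalent insulin rates
#' @param nutrition data.frame with columns `time` (min) and `rate` (g/h):
#'   piecewise-constant enteral/parenteral carbohydrate rates
#' @param admission_time ICU admission time (min)
#' @param therapy_start glycaemic-control start time (min),
#'   `>= admission_time`
#' @param diabetic_status `"none"`, `"type1"` or `"type2"`
#' @return An object of class `patient_record`.
#' @export
patient_record <- function(patient_id, outcome, bg, insulin, nutrition,
                           admission_time = 0, therapy_start = 0,
                           diabetic_status = "none") {
  outcome <- match.arg(outcome, c("survivor", "non-survivor"))
  diabetic_status <- match.arg(diabetic_status, c("none", "type1", "type2"))
  bg <- as.data.frame(bg); insulin <- as.data.frame(insulin)
  nutrition <- as.data.frame(nutrition)
  stopifnot(all(c("time", "value") %in% names(bg)),
            all(c("time", "rate") %in% names(insulin)),
            all(c("time", "rate") %in% names(nutrition)))
  if (nrow(bg) && any(diff(bg$time) <= 0)) {
    .stopf("patient %s: bg times must be strictly increasing", patient_id)
  }
  if (nrow(bg) && any(bg$value <= 0)) {
    .stopf("patient %s: bg values must be > 0", patient_id)
  }
  if (any(insulin$rate < 0) || any(nutrition$rate < 0)) {
    .stopf("patient %s: input rates must be >= 0", patient_id)
  }
  if (therapy_start < admission_time) {
    .stopf("patient %s: therapy_start must be >= admission_time", patient_id)
  }
  structure(list(patient_id = as.character(patient_id), outcome = outcome,
                 admission_time = admission_time, therapy_start = therapy_start,
                 bg = bg[, c("time", "value")],
                 insulin = insulin[, c("time", "rate")],
                 nutrition = nutrition[, c("time", "rate")],
                 diabetic_status = diabetic_status),
            class = "patient_record")
}

#' @export
print.patient_record <- function(x, ...) {
  cat(sprintf("Patient %s (%s): %d BG measurements over %.1f h of therapy\n",
              x$patient_id, x$outcome, nrow(x$bg),
              (max(x$bg$time) - x$therapy_start) / 60))
  invisible(x)
}

#' Build the model-unit input schedule of a record
#'
#' Merges a record's insulin (U/h) and nutrition (g/h) step schedules into a
#' single [input_schedule()] in model units (mU/min, mmol/min) on the union of
#' their breakpoints.
#'
#' @param record a [patient_record()]
#' @return An [input_schedule()] with times in minutes (same clock as the
#'   record).
#' @export
record_schedule <- function(record) {
  times <- sort(unique(c(record$insulin$time, record$nutrition$time)))
  if (!length(times)) times <- record$therapy_start
  step_val <- function(df, t) {
    if (!nrow(df)) return(rep(0, length(t)))
    i <- findInterval(t, df$time)
    ifelse(i < 1L, 0, df$rate[pmax(i, 1L)])
  }
  input_schedule(
    times,
    u_ex = insulin_u_per_h_to_mu_per_min(step_val(record$insulin, times)),
    P = carb_g_per_h_to_mmol_per_min(step_val(record$nutrition, times))
  )
}

#' Read patient records from the long-format CSV dialect
#'
#' The data file is long format with columns `patient_id`,
#' `signal` (one of `bg`, `insulin`, `nutrition`), `time_min`, `value`
#' (BG in mmol/L, insulin in U/h, nutrition in g/h). The metadata file has
#' columns `patient_id`, `outcome`, `admission_time`, `therapy_start`,
#' `diabetic_status`. Both are UTF-8 with a header row.
#'
#' @param data_path path to the long-format signals CSV
#' @param meta_path path to the metadata CSV
#' @return named list of [patient_record()] objects.
#' @export
read_patient_records <- function(data_path, meta_path) {
  dat <- utils::read.csv(data_path, stringsAsFactors = FALSE)
  meta <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
  need_d <- c("patient_id", "signal", "time_min", "value")
  need_m <- c("patient_id", "outcome", "admission_time", "therapy_start",
              "diabetic_status")
  if (!all(need_d %in% names(dat))) {
    .stopf("signals CSV must have columns: %s", paste(need_d, collapse = ", "))
  }
  if (!all(need_m %in% names(meta))) {
    .stopf("metadata CSV must have columns: %s", paste(need_m, collapse = ", "))
  }
  recs <- lapply(seq_len(nrow(meta)), function(i) {
    m <- meta[i, ]
    d <- dat[dat$patient_id == m$patient_id, ]
    pull <- function(sig, val_col) {
      s <- d[d$signal == sig, ]
      s <- s[order(s$time_min), ]
      out <- data.frame(time = s$time_min, v = s$value)
      names(out)[2L] <- val_col
      out
    }
    patient_record(m$patient_id, m$outcome,
                   bg = pull("bg", "value"),
                   insulin = pull("insulin", "rate"),
                   nutrition = pull("nutrition", "rate"),
                   admission_time = m$admission_time,
                   therapy_start = m$therapy_start,
                   diabetic_status = m$diabetic_status)
  })
  names(recs) <- meta$patient_id
  recs
}

#' Write patient records to the long-format CSV dialect
#'
#' Inverse of [read_patient_records()].
#'
#' @param records list of [patient_record()] objects
#' @param data_path output path for the signals CSV
#' @param meta_path output path for the metadata CSV
#' @return Invisibly, `c(data_path, meta_path)`.
#' @export
write_patient_records <- function(records, data_path, meta_path) {
  rows <- lapply(records, function(r) {
    rbind(
      data.frame(patient_id = r$patient_id, signal = "bg",
                 time_min = r$bg$time, value = r$bg$value),
      data.frame(patient_id = r$patient_id, signal = "insulin",
                 time_min = r$insulin$time, value = r$insulin$rate),
      data.frame(patient_id = r$patient_id, signal = "nutrition",
                 time_min = r$nutrition$time, value = r$nutrition$rate)
    )
  })
  meta <- do.call(rbind, lapply(records, function(r) {
    data.frame(patient_id = r$patient_id, outcome = r$outcome,
               admission_time = r$admission_time,
               therapy_start = r$therapy_start,
               diabetic_status = r$diabetic_status)
  }))
  utils::write.csv(do.call(rbind, rows), data_path, row.names = FALSE)
  utils::write.csv(meta, meta_path, row.names = FALSE)
  invisible(c(data_path, meta_path))
}
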