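# Preprocessing: valid-day marking, linear interpolation of missing hours,
# and assembly of retained PHQ-8 intervals.

#' Preprocessing settings
#'
#' @param min_hours minimum observed hourly slots for a day to count as valid
#'   (default 12, i.e. half the day).
#' @param min_valid_days minimum valid days for an interval to be retained
#'   (default 10 of the 14).
#' @param window_days questionnaire look-back window length (default 14); the
#'   window is the `window_days` calendar days strictly before the
#'   questionnaire date.
#' @param cutoff_date questionnaire records on or after this date are
#'   excluded (default `2020-02-01`); set to `NULL` to disable.
#' @return list of class `interval_settings`.
#' @export
interval_settings <- function(min_hours = 12, min_valid_days = 10,
                              window_days = 14,
                              cutoff_date = as.Date("2020-02-01")) {
  if (min_hours < 1 || min_hours > 24)
    stop_validation("min_hours must be in 1..24")
  if (min_valid_days < 1 || min_valid_days > window_days)
    stop_validation("min_valid_days must be in 1..window_days")
  structure(list(min_hours = as.integer(min_hours),
                 min_valid_days = as.integer(min_valid_days),
                 window_days = as.integer(window_days),
                 cutoff_date = if (is.null(cutoff_date)) NULL
                               else as.Date(cutoff_date)),
            class = "interval_settings")
}

# One participant's scans -> per-day, per-hour observed values. Multiple
# scans falling in the same clock-hour slot are averaged and rounded half-up.
# Returns a data.frame(date, hour, value).
.hour_slots <- function(scans) {
  ts <- parse_timestamp(scans$timestamp)
  if (anyNA(ts)) {
    bad <- which(is.na(ts))
    stop_validation("unparseable timestamp at scan row(s) %s (e.g. '%s')",
                    paste(utils::head(bad, 5), collapse = ", "),
                    scans$timestamp[bad[1]])
  }
  if (any(scans$count < 0))
    stop_validation("negative NBDC count at scan row(s) %s",
                    paste(utils::head(which(scans$count < 0), 5), collapse = ", "))
  date <- as.Date(ts, tz = "UTC")
  hour <- as.integer(format(ts, "%H", tz = "UTC"))
  agg <- stats::aggregate(scans$count, by = list(date = date, hour = hour), FUN = mean)
  agg$x <- round_half_up(agg$x)
  names(agg)[3] <- "value"
  agg[order(agg$date, agg$hour), ]
}

#' Mark valid days in a scan series
#'
#' A calendar day is valid when it holds at least `min_hours` distinct
#' observed hourly slots. One row is returned for every day in the scan
#' range, including days with no scans at all.
#'
#' @param scan_series data.frame with columns `timestamp` (ISO-8601) and
#'   `count` (non-negative) for a single participant.
#' @param min_hours validity threshold, default 12.
#' @return data.frame with `date`, `observed_hours`, `is_valid`.
#' @export
mark_valid_days <- function(scan_series, min_hours = 12) {
  slots <- .hour_slots(scan_series)
  all_days <- seq(min(slots$date), max(slots$date), by = "day")
  counts <- table(factor(as.character(slots$date),
                         levels = as.character(all_days)))
  data.frame(date = all_days,
             observed_hours = as.integer(counts),
             is_valid = as.integer(counts) >= min_hours,
             row.names = NULL)
}

#' Linearly interpolate the missing hours of a valid day
#'
#' Interior gaps are filled linearly between the nearest observed neighbours;
#' leading and trailing gaps take the nearest observed value (linear
#' interpolation is undefined with a single anchor). Observed values pass
#' through unchanged.
#'
#' @param hours numeric vector of length 24, `NA` where unobserved.
#' @param min_hours contract guard: at least this many observed values must be
#'   present (the caller should only pass valid days).
#' @return numeric vector of length 24 with no missing values.
#' @export
interpolate_day <- function(hours, min_hours = 12) {
  if (length(hours) != 24L)
    stop_validation("a day must have 24 hourly slots, got %d", length(hours))
  obs <- which(!is.na(hours))
  if (length(obs) < min_hours)
    stop_runtime("interpolate_day called on an invalid day (%d < %d observed hours)",
                 length(obs), min_hours)
  if (length(obs) == 24L) return(hours)
  stats::approx(obs, hours[obs], xout = 1:24, method = "linear", rule = 2)$y
}

#' PHQ-8 severity level
#'
#' Bins a PHQ-8 total score into the five conventional severity levels:
#' asymptomatic (<5), mild (5-9), moderate (10-14), moderately severe
#' (15-19) and severe (>=20).
#'
#' @param phq8_score integer vector in 0..24.
#' @return factor with the five ordered severity levels.
#' @export
severity_level <- function(phq8_score) {
  if (any(is.na(phq8_score)) || any(phq8_score != round(phq8_score)) ||
      any(phq8_score < 0 | phq8_score > 24))
    stop_validation("PHQ-8 scores must be integers in [0, 24]")
  cut(phq8_score, breaks = c(-Inf, 4.5, 9.5, 14.5, 19.5, Inf),
      labels = c("asymptomatic", "mild", "moderate",
                 "moderately severe", "severe"),
      ordered_result = TRUE)
}

#' Build retained PHQ-8 intervals from raw tables
#'
#' Applies the inclusion criteria: questionnaire records before the cutoff
#' date; a look-back window of `window_days` calendar days strictly before
#' the questionnaire date; days with at least `min_hours` observed hourly
#' slots are valid; intervals with at least `min_valid_days` valid days are
#' retained. Missing hours within valid days are linearly interpolated,
#' invalid days are discarded, and the remaining days are concatenated
#' chronologically into one sequence of length `24 * valid_days`.
#'
#' @param scans data.frame `participant_id`, `timestamp`, `count`.
#' @param phq8 data.frame `participant_id`, `date`, `score`.
#' @param demographics data.frame `participant_id`, `age`, `gender`,
#'   `education_years` (carried through; participants missing here are
#'   rejected because demographics are model covariates downstream).
#' @param settings an [interval_settings()].
#'
#' @return object of class `nbdc_intervals`: list with `intervals` (one row
#'   of metadata per retained interval), `sequences` (named list of numeric
#'   sequences keyed by `interval_id`), `rejections` (one row per dropped
#'   questionnaire record with the failed criterion) and `settings`.
#' @export
build_intervals <- function(scans, phq8, demographics,
                            settings = interval_settings()) {
  stopifnot(inherits(settings, "interval_settings"))
  validate_scans(scans)
  validate_phq8(phq8)
  validate_demographics(demographics)
  phq8$date <- as.Date(phq8$date)
  keep <- list(); seqs <- list(); rej <- list()
  slot_cache <- list()
  for (pid in unique(phq8$participant_id)) {
    p_phq8 <- phq8[phq8$participant_id == pid, , drop = FALSE]
    p_scans <- scans[scans$participant_id == pid, , drop = FALSE]
    has_demo <- pid %in% demographics$participant_id
    slots <- if (nrow(p_scans)) .hour_slots(p_scans) else NULL
    for (k in seq_len(nrow(p_phq8))) {
      qdate <- p_phq8$date[k]
      score <- p_phq8$score[k]
      reject <- function(reason) {
        rej[[length(rej) + 1L]] <<- data.frame(
          participant_id = pid, questionnaire_date = qdate, reason = reason)
      }
      if (!is.null(settings$cutoff_date) && qdate >= settings$cutoff_date) {
        reject("on_or_after_cutoff"); next
      }
      if (!has_demo) { reject("missing_demographics"); next }
      win <- seq(qdate - settings$window_days, qdate - 1, by = "day")
      wslots <- if (is.null(slots)) NULL
                else slots[slots$date %in% win, , drop = FALSE]
      if (is.null(wslots) || nrow(wslots) == 0L) {
        reject("no_scans_in_window"); next
      }
      per_day <- split(wslots, as.character(wslots$date))
      valid_days <- names(per_day)[vapply(per_day, nrow, 0L) >= settings$min_hours]
      if (length(valid_days) < settings$min_valid_days) {
        reject("too_few_valid_days"); next
      }
      valid_days <- sort(valid_days)
      seq_vals <- unlist(lapply(valid_days, function(d) {
        day <- per_day[[d]]
        hours <- rep(NA_real_, 24)
        hours[day$hour + 1L] <- day$value
        interpolate_day(hours, settings$min_hours)
      }), use.names = FALSE)
      iid <- paste(pid, format(qdate, "%Y-%m-%d"), sep = "_")
      keep[[length(keep) + 1L]] <- data.frame(
        interval_id = iid, participant_id = pid, questionnaire_date = qdate,
        phq8_score = score,
        severity_level = as.character(severity_level(score)),
        valid_days = length(valid_days), seq_length = length(seq_vals))
      seqs[[iid]] <- seq_vals
    }
  }
  empty_meta <- data.frame(interval_id = character(),
                           participant_id = character(),
                           questionnaire_date = as.Date(character()),
                           phq8_score = integer(), severity_level = character(),
                           valid_days = integer(), seq_length = integer())
  structure(list(
    intervals = if (length(keep)) do.call(rbind, keep) else empty_meta,
    sequences = seqs,
    rejections = if (length(rej)) do.call(rbind, rej) else
      data.frame(participant_id = character(),
                 questionnaire_date = as.Date(character()),
                 reason = character()),
    settings = settings), class = "nbdc_intervals")
}

#' @export
print.nbdc_intervals <- function(x, ...) {
  cat(sprintf("<nbdc_intervals> %d retained interval(s), %d rejection(s)\n",
              nrow(x$intervals), nrow(x$rejections)))
  invisible(x)
}
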