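# Synthetic cohort generator: hourly nearby-Bluetooth-device-count (NBDC)
# series, biweekly PHQ-8 trajectories and baseline demographics with the
# statistical structure the downstream analysis assumes.

#' Configuration for a synthetic NBDC/PHQ-8 cohort
#'
#' Bundles every knob of the generator. Defaults describe the study design the
#' pipeline targets: biweekly PHQ-8 questionnaires over a four-month follow-up
#' (a median of 8 intervals per participant), hourly Bluetooth scans with
#' moderate missingness, and latent-severity coupling in the four directions
#' the association analysis interprets — as severity rises the amount of the
#' NBDC decreases, its variance decreases, its circadian periodicity weakens,
#' and the sequence becomes more irregular.
#'
#' @param n_participants number of participants.
#' @param followup_days follow-up length in days.
#' @param questionnaire_period_days days between questionnaires (default 14).
#' @param seed integer seed; the whole cohort is reproducible from it.
#' @param start_date first day of follow-up (`Date`).
#' @param missing_hour_rate probability that an individual hourly scan is lost.
#' @param missing_day_rate probability that a whole day of scans is lost.
#' @param severity_coupling named list of dimensionless effect sizes
#'   (`amount`, `variance`, `amplitude`, `irregularity`) scaling how strongly
#'   the latent severity moves each channel; set all to 0 for a null cohort.
#' @param phq8_ar_coef autoregression coefficient of the latent severity
#'   process, in `[0, 1)` (1 is allowed only with zero innovation noise, the
#'   degenerate constant trajectory).
#' @param phq8_noise_sd innovation standard deviation of the latent process,
#'   in PHQ-8 score units.
#' @param baseline_mean,baseline_sd population mean / sd of participants'
#'   long-run latent severity (score units).
#' @param log_intensity_mean,log_intensity_sd population distribution of the
#'   participant-level log mean hourly device count.
#' @param circadian_amplitude population mean circadian amplitude on the log
#'   scale at zero severity.
#' @param weekday_effect additive log-intensity bonus on weekdays.
#' @param noise_sd baseline hour-level log-normal overdispersion sd.
#' @param phase_jitter_sd baseline day-to-day circadian phase jitter (hours).
#' @param gender_female_prop proportion of female participants (cohorts in
#'   this setting are typically about three-quarters female).
#'
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 316,
                          followup_days = 112,
                          questionnaire_period_days = 14,
                          seed = 1L,
                          start_date = as.Date("2019-01-01"),
                          missing_hour_rate = 0.08,
                          missing_day_rate = 0.08,
                          severity_coupling = list(amount = 1.0, variance = 0.5,
                                                   amplitude = 0.8,
                                                   irregularity = 1.0),
                          phq8_ar_coef = 0.6,
                          phq8_noise_sd = 2.5,
                          baseline_mean = 9,
                          baseline_sd = 5,
                          log_intensity_mean = log(4),
                          log_intensity_sd = 0.4,
                          circadian_amplitude = 1.0,
                          weekday_effect = 0.25,
                          noise_sd = 0.3,
                          phase_jitter_sd = 0.5,
                          gender_female_prop = 0.741) {
  if (n_participants < 1 || followup_days < 1)
    stop_validation("n_participants and followup_days must be positive counts")
  if (questionnaire_period_days < 1)
    stop_validation("questionnaire_period_days must be a positive count")
  for (p in c(missing_hour_rate, missing_day_rate, gender_female_prop))
    if (p < 0 || p > 1) stop_validation("rates must be probabilities in [0,1]")
  if (phq8_ar_coef < 0 || phq8_ar_coef > 1 ||
      (phq8_ar_coef == 1 && phq8_noise_sd > 0))
    stop_validation("phq8_ar_coef must lie in [0,1) (1 only with zero noise)")
  if (phq8_noise_sd < 0) stop_validation("phq8_noise_sd must be >= 0")
  need <- c("amount", "variance", "amplitude", "irregularity")
  if (!all(need %in% names(severity_coupling)))
    stop_validation("severity_coupling needs channels: %s",
                    paste(need, collapse = ", "))
  if (followup_days < questionnaire_period_days)
    stop_validation("follow-up must cover at least one questionnaire period")
  structure(
    list(n_participants = as.integer(n_participants),
         followup_days = as.integer(followup_days),
         questionnaire_period_days = as.integer(questionnaire_period_days),
         seed = as.integer(seed), start_date = as.Date(start_date),
         missing_hour_rate = missing_hour_rate,
         missing_day_rate = missing_day_rate,
         severity_coupling = severity_coupling,
         phq8_ar_coef = phq8_ar_coef, phq8_noise_sd = phq8_noise_sd,
         baseline_mean = baseline_mean, baseline_sd = baseline_sd,
         log_intensity_mean = log_intensity_mean,
         log_intensity_sd = log_intensity_sd,
         circadian_amplitude = circadian_amplitude,
         weekday_effect = weekday_effect, noise_sd = noise_sd,
         phase_jitter_sd = phase_jitter_sd,
         gender_female_prop = gender_female_prop),
    class = "cohort_config")
}

#' Simulate one participant's PHQ-8 trajectory
#'
#' The latent severity follows a mean-reverting AR(1) process around the
#' participant's long-run level; scores are the latent values clipped to the
#' 0-24 questionnaire range and rounded to integers. Questionnaires are spaced
#' `questionnaire_period_days` apart starting one period after follow-up
#' begins, mirroring a biweekly mobile-phone questionnaire schedule.
#'
#' @param config a [cohort_config()].
#' @param participant_seed optional integer; when given, the RNG is seeded so
#'   the trajectory is reproducible in isolation.
#' @param baseline optional long-run latent severity (score units); drawn from
#'   the population distribution when `NULL`.
#'
#' @return data.frame with columns `occasion`, `date`, `score` (integer 0-24)
#'   and `latent` (the unclipped AR(1) state).
#' @export
generate_phq8_trajectory <- function(config, participant_seed = NULL,
                                     baseline = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  if (!is.null(participant_seed)) set.seed(as.integer(participant_seed))
  n_q <- floor(config$followup_days / config$questionnaire_period_days)
  if (n_q < 1) stop_validation("follow-up shorter than one questionnaire period")
  mu <- baseline %||%
    min(24, max(0, stats::rnorm(1, config$baseline_mean, config$baseline_sd)))
  phi <- config$phq8_ar_coef
  z <- numeric(n_q)
  z[1] <- mu + stats::rnorm(1, 0, config$phq8_noise_sd)
  for (t in seq_len(n_q)[-1])
    z[t] <- mu + phi * (z[t - 1] - mu) + stats::rnorm(1, 0, config$phq8_noise_sd)
  data.frame(
    occasion = seq_len(n_q),
    date = config$start_date + seq_len(n_q) * config$questionnaire_period_days,
    score = as.integer(round_half_up(pmin(24, pmax(0, z)))),
    latent = z)
}

# Map a day index (0-based from start of follow-up) to the questionnaire
# occasion whose 14-day window it falls in; days past the last questionnaire
# inherit the last occasion's severity.
.day_occasion <- function(day, period, n_q) pmin(floor(day / period) + 1L, n_q)

#' Simulate one participant's hourly NBDC series
#'
#' Hourly counts are Poisson with a log-link intensity combining a participant
#' baseline, a 24-hour circadian sinusoid, a weekday term and log-normal
#' hour-level noise. The participant's latent severity in the surrounding
#' questionnaire window modulates the intensity through the four coupling
#' channels: `amount` lowers the log baseline, `amplitude` shrinks the
#' circadian sinusoid, `variance` damps the hour-level noise, and
#' `irregularity` adds day-level phase jitter plus extra overdispersion.
#' Whole days and single hours are then removed at the configured missing
#' rates.
#'
#' @param participant list with at least `participant_id`, `log_intensity`
#'   (participant log baseline), `amplitude0` (participant circadian
#'   amplitude) and `latent_severity_path` (one latent value per
#'   questionnaire occasion), as produced inside [generate_cohort()].
#' @param config a [cohort_config()].
#'
#' @return data.frame with columns `participant_id`, `timestamp` (ISO-8601
#'   UTC, on the hour) and `count` (non-negative integer).
#' @export
generate_nbdc_series <- function(participant, config) {
  stopifnot(inherits(config, "cohort_config"))
  cpl <- config$severity_coupling
  n_q <- length(participant$latent_severity_path)
  days <- seq_len(config$followup_days) - 1L
  occ <- .day_occasion(days, config$questionnaire_period_days, n_q)
  sev <- pmin(1, pmax(0, participant$latent_severity_path[occ] / 24))
  dates <- config$start_date + days
  weekday <- !(format(dates, "%u") %in% c("6", "7"))
  out <- vector("list", length(days))
  for (i in seq_along(days)) {
    s <- sev[i]
    amp <- max(0, participant$amplitude0 * (1 - cpl$amplitude * s))
    jitter_sd <- config$phase_jitter_sd + 3 * cpl$irregularity * s
    phase <- stats::rnorm(1, 0, jitter_sd)
    eps_sd <- config$noise_sd * max(0.1, 1 - cpl$variance * s) +
      0.25 * cpl$irregularity * s
    h <- 0:23
    log_mu <- participant$log_intensity - cpl$amount * s +
      amp * cos(2 * pi * (h - 13 - phase) / 24) +
      config$weekday_effect * weekday[i] +
      stats::rnorm(24, 0, eps_sd)
    counts <- stats::rpois(24, exp(log_mu))
    # missingness is drawn even for dropped days to keep one RNG stream per day
    drop_day <- stats::runif(1) < config$missing_day_rate
    drop_hour <- stats::runif(24) < config$missing_hour_rate
    keep <- if (drop_day) rep(FALSE, 24) else !drop_hour
    if (!any(keep)) next
    out[[i]] <- data.frame(
      participant_id = participant$participant_id,
      timestamp = sprintf("%sT%02d:00:00Z", format(dates[i], "%Y-%m-%d"), h[keep]),
      count = counts[keep])
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res))
    res <- data.frame(participant_id = character(), timestamp = character(),
                      count = integer())
  rownames(res) <- NULL
  res
}

#' Generate a full synthetic cohort
#'
#' Draws demographics, PHQ-8 trajectories and hourly NBDC series for every
#' participant, all from the single seed in `config`, and optionally writes
#' the three CSV exports (`scans.csv`, `phq8.csv`, `demographics.csv`).
#' Output is byte-identical across runs with the same configuration.
#'
#' @param config a [cohort_config()].
#' @param out_dir optional directory; when given the three CSVs are written
#'   there (created if needed).
#'
#' @return list with data.frames `scans` (participant_id, timestamp, count),
#'   `phq8` (participant_id, date, score), `demographics` (participant_id,
#'   age, gender, education_years), the per-participant `latent` severity
#'   paths, and the `config`.
#' @export
generate_cohort <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_participants
  ids <- sprintf("P%04d", seq_len(n))
  if (anyDuplicated(ids)) stop_validation("duplicate participant ids generated")
  demographics <- data.frame(
    participant_id = ids,
    age = pmin(75, pmax(18, round(stats::rnorm(n, 48, 13)))),
    gender = ifelse(stats::runif(n) < config$gender_female_prop,
                    "female", "male"),
    education_years = pmin(25, pmax(6, round(stats::rnorm(n, 16, 3)))))
  scans <- vector("list", n)
  phq8 <- vector("list", n)
  latent <- vector("list", n)
  for (i in seq_len(n)) {
    traj <- generate_phq8_trajectory(config)
    part <- list(
      participant_id = ids[i],
      log_intensity = stats::rnorm(1, config$log_intensity_mean,
                                   config$log_intensity_sd),
      amplitude0 = max(0, stats::rnorm(1, config$circadian_amplitude, 0.2)),
      latent_severity_path = traj$latent)
    scans[[i]] <- generate_nbdc_series(part, config)
    phq8[[i]] <- data.frame(participant_id = ids[i],
                            date = format(traj$date, "%Y-%m-%d"),
                            score = traj$score)
    latent[[i]] <- traj$latent
  }
  cohort <- list(scans = do.call(rbind, scans),
                 phq8 = do.call(rbind, phq8),
                 demographics = demographics,
                 latent = stats::setNames(latent, ids),
                 config = config)
  rownames(cohort$scans) <- rownames(cohort$phq8) <- NULL
  if (!is.null(out_dir)) write_cohort(cohort, out_dir)
  cohort
}

#' Write a cohort's three CSV exports
#'
#' @param cohort result of [generate_cohort()].
#' @param out_dir output directory, created if missing.
#' @return `out_dir`, invisibly.
#' @export
write_cohort <- function(cohort, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort$scans, file.path(out_dir, "scans.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$phq8, file.path(out_dir, "phq8.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$demographics,
                   file.path(out_dir, "demographics.csv"), row.names = FALSE)
  invisible(out_dir)
}
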