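test_that("valid-day marking respects the 12-hour threshold boundary", {
  q <- as.Date("2019-03-01")
  scans <- rbind(make_scans("P1", q, 1, hours = 0:23),          # 24 h
                 make_scans("P1", q - 1, 1, hours = 0:11),      # 12 h
                 make_scans("P1", q - 2, 1, hours = 0:10))      # 11 h
  vd <- mark_valid_days(scans)
  vd <- vd[order(vd$date, decreasing = TRUE), ]
  expect_equal(vd$observed_hours[1:3], c(24L, 12L, 11L))
  expect_equal(vd$is_valid[1:3], c(TRUE, TRUE, FALSE))
})

test_that("days with no scans appear as invalid rows in the mask", {
  scans <- rbind(make_scans("P1", as.Date("2019-03-05"), 1),
                 make_scans("P1", as.Date("2019-03-01"), 1))
  vd <- mark_valid_days(scans)
  expect_equal(nrow(vd), 5)    # full calendar range
  expect_equal(sum(vd$observed_hours == 0), 3)
})

test_that("unparseable timestamps raise a row-level validation error", {
  scans <- make_scans("P1", as.Date("2019-03-01"), 1)
  scans$timestamp[5] <- "not-a-time"
  expect_error(mark_valid_days(scans), "row.*5")
})

test_that("interior gaps interpolate linearly and edges extend nearest values", {
  h <- rep(NA_real_, 24)
  h[c(1, 3)] <- c(2, 4)              # hours 0 and 2 observed
  h[4:24] <- 6
  out <- interpolate_day(h, min_hours = 12)
  expect_equal(out[2], 3)            # linear midpoint
  full <- as.numeric(1:24)
  expect_identical(interpolate_day(full), full)   # identity on complete days
  lead <- rep(7, 24); lead[1:3] <- NA; lead[4] <- 7
  expect_equal(interpolate_day(lead, min_hours = 12)[1:3], rep(7, 3))
  expect_error(interpolate_day(c(rep(1, 11), rep(NA_real_, 13)),
                               min_hours = 12), "invalid day")
})

test_that("multiple scans in one clock hour are averaged then rounded half-up", {
  scans <- make_scans("P1", as.Date("2019-03-01"), 1, hours = 0:23, count = 4)
  extra <- data.frame(participant_id = "P1",
                      timestamp = "2019-02-28T05:30:00Z", count = 5)
  vd <- mark_valid_days(rbind(scans, extra))
  # the 05:30 scan falls in an already observed hour slot of the same day
  expect_equal(nrow(vd[vd$observed_hours > 0, ]), 1)
  expect_equal(vd$observed_hours[vd$observed_hours > 0], 24L)
  # via build_intervals the 4 and 5 in hour 5 become round_half_up(4.5) = 5
  phq8 <- data.frame(participant_id = "P1", date = "2019-03-01", score = 3)
  demo <- data.frame(participant_id = "P1", age = 40, gender = "female",
                     education_years = 15)
  scans2 <- rbind(make_scans("P1", as.Date("2019-03-01"), 10, count = 4), extra)
  iv <- build_intervals(scans2, phq8, demo)
  seq1 <- iv$sequences[[1]]
  expect_equal(sort(unique(seq1)), c(4, 5))
  expect_equal(sum(seq1 == 5), 1)
})

test_that("interval retention follows the valid-day thresholds", {
  phq8 <- data.frame(participant_id = "P1", date = "2019-03-01", score = 7)
  demo <- data.frame(participant_id = "P1", age = 40, gender = "female",
                     education_years = 15)
  for (case in list(list(days = 14, keep = TRUE, len = 336),
                    list(days = 10, keep = TRUE, len = 240),
                    list(days = 9, keep = FALSE, len = NA))) {
    scans <- make_scans("P1", as.Date("2019-03-01"), case$days)
    iv <- build_intervals(scans, phq8, demo)
    if (case$keep) {
      expect_equal(nrow(iv$intervals), 1)
      expect_equal(iv$intervals$seq_length, case$len)
      expect_equal(length(iv$sequences[[1]]), case$len)
    } else {
      expect_equal(nrow(iv$intervals), 0)
      expect_equal(iv$rejections$reason, "too_few_valid_days")
    }
  }
})

test_that("the questionnaire day itself is outside the look-back window", {
  # 13 days before the questionnaire plus the questionnaire day itself:
  # only the 13 prior days count, so the interval is retained with 13 days
  scans <- rbind(make_scans("P1", as.Date("2019-03-01"), 13),
                 make_scans("P1", as.Date("2019-03-02"), 1))  # the q-day
  phq8 <- data.frame(participant_id = "P1", date = "2019-03-01", score = 7)
  demo <- data.frame(participant_id = "P1", age = 40, gender = "female",
                     education_years = 15)
  iv <- build_intervals(scans, phq8, demo)
  expect_equal(iv$intervals$valid_days, 13)
})

test_that("questionnaires on or after the cutoff date are excluded", {
  scans <- make_scans("P1", as.Date("2020-02-01"), 14)
  phq8 <- data.frame(participant_id = "P1", date = "2020-02-01", score = 7)
  demo <- data.frame(participant_id = "P1", age = 40, gender = "female",
                     education_years = 15)
  iv <- build_intervals(scans, phq8, demo)
  expect_equal(nrow(iv$intervals), 0)
  expect_equal(iv$rejections$reason, "on_or_after_cutoff")
  iv2 <- build_intervals(scans, phq8, demo,
                         interval_settings(cutoff_date = "2020-03-01"))
  expect_equal(nrow(iv2$intervals), 1)
})

test_that("PHQ-8 severity levels follow the five half-open bins", {
  expect_equal(as.character(severity_level(c(0, 4, 5, 7, 9, 10, 14, 15, 19, 20, 24))),
               c("asymptomatic", "asymptomatic", "mild", "mild", "mild",
                 "moderate", "moderate", "moderately severe",
                 "moderately severe", "severe", "severe"))
  expect_error(severity_level(25), "0, 24")
  expect_error(severity_level(-1), "0, 24")
  expect_error(severity_level(3.5), "integers")
})

test_that("out-of-range scores are a validation error, not a rejection", {
  scans <- make_scans("P1", as.Date("2019-03-01"), 14)
  phq8 <- data.frame(participant_id = "P1", date = "2019-03-01", score = 25)
  demo <- data.frame(participant_id = "P1", age = 40, gender = "female",
                     education_years = 15)
  expect_error(build_intervals(scans, phq8, demo),
               class = "nbdc_validation_error")
})

test_that("retained sequences are complete with length 24 x valid_days", {
  co <- generate_cohort(cohort_config(n_participants = 8, followup_days = 56,
                                      seed = 21))
  iv <- build_intervals(co$scans, co$phq8, co$demographics)
  expect_gt(nrow(iv$intervals), 0)
  for (i in seq_len(nrow(iv$intervals))) {
    s <- iv$sequences[[iv$intervals$interval_id[i]]]
    expect_false(anyNA(s))
    expect_equal(length(s), 24 * iv$intervals$valid_days[i])
    expect_gte(iv$intervals$valid_days[i], 10)
  }
})

test_that("with no missingness every full window is retained", {
  co <- generate_cohort(cohort_config(n_participants = 6, followup_days = 56,
                                      missing_hour_rate = 0,
                                      missing_day_rate = 0, seed = 22))
  iv <- build_intervals(co$scans, co$phq8, co$demographics)
  # every questionnaire window lies fully inside follow-up and is complete
  expect_equal(nrow(iv$intervals), nrow(co$phq8))
  expect_true(all(iv$intervals$valid_days == 14))
})
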