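# Shared fixture builders and independent oracles, all generated in code.

# Naive O(N^2) double-loop template-counting sample entropy; the independent
# oracle for the vectorized implementation.
sampen_brute <- function(x, m, r) {
  n <- length(x)
  nt <- n - m
  A <- 0; B <- 0
  for (i in 1:(nt - 1)) for (j in (i + 1):nt) {
    if (max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)])) <= r) B <- B + 1
    if (max(abs(x[i:(i + m)] - x[j:(j + m)])) <= r) A <- A + 1
  }
  if (A == 0 || B == 0) return(-log(2 / (nt * (nt - 1))))
  -log(A / B)
}

# Scan rows for one participant: `days` calendar days before `qdate`, each
# with the given hours observed and constant (or supplied) counts.
make_scans <- function(pid, qdate, n_days, hours = 0:23, count = 5) {
  qdate <- as.Date(qdate)
  do.call(rbind, lapply(seq_len(n_days), function(d) {
    day <- qdate - d
    data.frame(participant_id = pid,
               timestamp = sprintf("%sT%02d:00:00Z", format(day), hours),
               count = count)
  }))
}

# Minimal interval table for CV-plan tests: participant i gets t_i intervals
# 14 days apart with the given scores.
make_interval_table <- function(counts, scores = NULL) {
  do.call(rbind, lapply(seq_along(counts), function(i) {
    t <- counts[i]
    sc <- if (is.null(scores)) ((seq_len(t) * 7) %% 20) else scores[[i]]
    pid <- sprintf("S%04d", i)
    data.frame(participant_id = pid,
               interval_id = sprintf("%s_%02d", pid, seq_len(t)),
               questionnaire_date = as.Date("2019-01-01") + 14 * seq_len(t),
               phq8_score = sc)
  }))
}

# Hierarchical linear data with a known population slope on one feature and
# an AR-style last-score column; used for sampler parameter recovery.
make_hier_linear <- function(seed, J = 60, t = 6, slope = 0.8,
                             last_slope = 0.5, noise = 0.5,
                             extra_features = character()) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(J), function(j) {
    a <- stats::rnorm(1, 0, 0.7)
    x <- stats::rnorm(t)
    l <- stats::rnorm(t)
    d <- data.frame(participant_id = sprintf("P%03d", j),
                    questionnaire_date = as.Date("2019-01-01") + 14 * seq_len(t),
                    phq8_score = a + last_slope * l + slope * x +
                      stats::rnorm(t, 0, noise),
                    last_phq8 = l, feat = x,
                    age = stats::rnorm(1, 48, 10),
                    gender = sample(c("male", "female"), 1),
                    education_years = stats::rnorm(1, 16, 3))
    for (f in extra_features) d[[f]] <- stats::rnorm(t)
    d
  }))
}

# Mixed-model screening data: random participant intercepts, one feature
# with a planted slope, demographic covariates with no effect.
make_lmm_data <- function(seed, J = 100, t = 8, slope = -0.5,
                          intercept_sd = 2, noise_sd = 3) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(J), function(j) {
    b0 <- 9 + stats::rnorm(1, 0, intercept_sd)
    x <- stats::rnorm(t)
    data.frame(participant_id = sprintf("P%03d", j),
               phq8_score = b0 + slope * x + stats::rnorm(t, 0, noise_sd),
               feat = x,
               age = stats::rnorm(1, 48, 12),
               gender = sample(c("male", "female"), 1),
               education_years = stats::rnorm(1, 16, 3))
  }))
}

# Feature table with all 49 named feature columns filled with noise (plus
# optional signal columns), for the nested-model ladder tests.
make_feature_table <- function(seed, J = 30, t = 4, signal = NULL,
                               signal_strength = 0) {
  set.seed(seed)
  feats <- nbdcdep::feature_names()
  do.call(rbind, lapply(seq_len(J), function(j) {
    d <- data.frame(participant_id = sprintf("P%03d", j),
                    questionnaire_date = as.Date("2019-01-01") + 14 * seq_len(t),
                    age = stats::rnorm(1, 48, 12),
                    gender = sample(c("male", "female"), 1),
                    education_years = stats::rnorm(1, 16, 3))
    for (f in feats) d[[f]] <- stats::rnorm(t)
    lin <- 9 + stats::rnorm(1, 0, 2)
    if (!is.null(signal))
      lin <- lin + signal_strength * rowSums(as.matrix(d[signal]))
    d$phq8_score <- lin + stats::rnorm(t, 0, 3)
    d
  }))
}
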