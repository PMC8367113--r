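test_that("prediction subset criteria apply at their boundaries", {
  iv <- make_interval_table(counts = c(3, 2, 5),
                            scores = list(c(4, 6, 9),          # range 5: in
                                          c(0, 20),            # 2 intervals: out
                                          c(8, 9, 10, 11, 12)))# range 4: out
  sub <- select_prediction_subset(iv)
  expect_equal(unique(sub$participant_id), "S0001")
  expect_equal(nrow(sub), 3)
})

test_that("LAO folds follow the rolling-origin scheme", {
  iv <- make_interval_table(counts = c(3, 5, 6),
                            scores = list(c(0, 10, 3), c(2, 9, 1, 8, 3),
                                          c(5, 11, 2, 9, 1, 7)))
  sub <- select_prediction_subset(iv)
  plan <- lao_splits(sub)
  expect_equal(length(plan$folds), 5)   # T - 1 with T = 6
  # the 3-interval participant is tested in folds for k = 2 and 3 only
  tested <- vapply(plan$folds, function(f)
    any(grepl("^S0001", f$test)), logical(1))
  expect_equal(tested, c(TRUE, TRUE, FALSE, FALSE, FALSE))
  # training for fold k holds exactly intervals 1..k-1 of tested participants
  expect_setequal(plan$folds[[2]]$train,
                  c("S0001_01", "S0001_02", "S0002_01", "S0002_02",
                    "S0003_01", "S0003_02"))
  expect_true(audit_cv_plan(plan, sub))
})

test_that("LOO folds train on two own intervals plus everyone else", {
  iv <- make_interval_table(counts = c(5, 3, 4),
                            scores = list(c(0, 10, 3, 8, 2), c(2, 9, 15),
                                          c(5, 11, 2, 9)))
  sub <- select_prediction_subset(iv)
  plan <- loo_splits(sub)
  expect_equal(length(plan$folds), 3)   # J folds
  f1 <- plan$folds[[1]]                  # S0001, t = 5
  expect_equal(sort(f1$test), c("S0001_03", "S0001_04", "S0001_05"))
  expect_true(all(c("S0001_01", "S0001_02") %in% f1$train))
  expect_false(any(f1$test %in% f1$train))
  expect_true(all(c("S0002_03", "S0003_04") %in% f1$train))
  expect_true(audit_cv_plan(plan, sub))
})

test_that("LOO refuses participants with fewer than three intervals", {
  iv <- make_interval_table(counts = c(2, 4),
                            scores = list(c(0, 10), c(2, 9, 1, 8)))
  expect_error(loo_splits(iv), "< 3 intervals")
})

test_that("the leakage audit catches a future-into-train violation", {
  iv <- make_interval_table(counts = c(4), scores = list(c(0, 10, 3, 8)))
  plan <- lao_splits(iv)
  plan$folds[[1]]$train <- c(plan$folds[[1]]$train, "S0001_04")
  expect_error(audit_cv_plan(plan, iv), "leakage")
})

test_that("the hierarchical sampler recovers a planted population slope", {
  d <- make_hier_linear(seed = 71, J = 60, t = 6, slope = 0.8)
  fit <- suppressWarnings(fit_hierarchical(
    d, c("feat", "age", "gender", "education_years"),
    hier_spec(draws = 600, warmup = 400, chains = 2, seed = 5)))
  cs <- coef_summary(fit)
  row <- cs[cs$predictor == "feat", ]
  expect_lt(abs(row$mean_raw - 0.8), 0.1)
  expect_true(row$lower_raw < 0.8 && row$upper_raw > 0.8)
  expect_true(all(is.finite(fit$rhat)))
})

test_that("shrinkage pulls all-noise feature slopes toward zero", {
  d <- make_hier_linear(seed = 72, J = 40, t = 5, slope = 0,
                        extra_features = paste0("noise", 1:10))
  fit <- suppressWarnings(fit_hierarchical(
    d, c("feat", paste0("noise", 1:10)),
    hier_spec(draws = 400, warmup = 300, chains = 2, seed = 6)))
  expect_lt(mean(abs(fit$beta_mean)), 0.5)   # below half the prior scale
})

test_that("fits are reproducible under a fixed sampler seed", {
  d <- make_hier_linear(seed = 73, J = 20, t = 4)
  sp <- hier_spec(draws = 200, warmup = 200, chains = 2, seed = 9)
  f1 <- suppressWarnings(fit_hierarchical(d, "feat", sp))
  f2 <- suppressWarnings(fit_hierarchical(d, "feat", sp))
  expect_identical(f1$pop_mean, f2$pop_mean)
  expect_identical(f1$alpha_mean, f2$alpha_mean)
})

test_that("the sampler agrees with an independent MCMC engine", {
  skip_if_not_installed("rjags")
  d <- make_hier_linear(seed = 74, J = 50, t = 6, slope = 0.8)
  fit <- suppressWarnings(fit_hierarchical(
    d, c("feat", "age"),
    hier_spec(draws = 1000, warmup = 500, chains = 2, seed = 3)))
  ys <- scale(d$phq8_score); l <- scale(d$last_phq8)[, 1]
  X <- scale(cbind(feat = d$feat, age = d$age))
  g <- match(d$participant_id, sort(unique(d$participant_id)))
  jd <- list(y = ys[, 1], X = X, l = l, g = g, n = nrow(d), J = max(g), p = 2,
             sig0 = 5 / attr(ys, "scaled:scale"))
  model_text <- "model{
    for (i in 1:n) {
      y[i] ~ dnorm(alpha[g[i]] + b[g[i]] * l[i] + inprod(X[i,], beta[]),
                   1 / sigma^2)
    }
    for (j in 1:J) {
      alpha[j] ~ dnorm(mua, 1 / taua^2)
      b[j] ~ dnorm(mub, 1 / taub^2)
    }
    for (k in 1:p) { beta[k] ~ dnorm(0, 1) }
    mua ~ dnorm(0, 1); mub ~ dnorm(0, 1)
    taua ~ dnorm(0, 1) T(0,); taub ~ dnorm(0, 1) T(0,)
    sigma ~ dnorm(0, 1 / sig0^2) T(0,)
  }"
  jm <- rjags::jags.model(textConnection(model_text), data = jd, n.chains = 2,
                          quiet = TRUE,
                          inits = list(.RNG.name = "base::Mersenne-Twister",
                                       .RNG.seed = 5))
  stats::update(jm, 1000, progress.bar = "none")
  ss <- rjags::coda.samples(jm, c("beta", "mub", "sigma"), 2000,
                            progress.bar = "none")
  jmeans <- colMeans(as.matrix(ss))
  expect_lt(abs(fit$pop_mean[["feat"]] - jmeans[["beta[1]"]]), 0.05)
  expect_lt(abs(fit$pop_mean[["age"]] - jmeans[["beta[2]"]]), 0.05)
  expect_lt(abs(fit$pop_mean[["mu_b"]] - jmeans[["mub"]]), 0.05)
  expect_lt(abs(fit$pop_mean[["sigma"]] - jmeans[["sigma"]]), 0.05)
})

test_that("predictions interpolate heavily replicated training rows", {
  # 30 near-identical participants, near-noiseless outcome
  d <- make_hier_linear(seed = 75, J = 30, t = 6, slope = 1, noise = 0.05)
  fit <- suppressWarnings(fit_hierarchical(
    d, "feat", hier_spec(draws = 400, warmup = 300, chains = 2, seed = 4)))
  test_row <- d[3, ]
  pred <- predict(fit, test_row)
  expect_lt(abs(pred - test_row$phq8_score), 0.5)
})

test_that("unseen participants fall back on population means and clipping holds", {
  d <- make_hier_linear(seed = 76, J = 25, t = 5)
  d$phq8_score <- pmin(24, pmax(0, 12 + 4 * d$phq8_score))
  fit <- suppressWarnings(fit_hierarchical(
    d, "feat", hier_spec(draws = 300, warmup = 200, chains = 2, seed = 8)))
  new1 <- data.frame(participant_id = "UNSEEN", last_phq8 = 10, feat = 0.2)
  new2 <- new1; new2$participant_id <- "ALSO_UNSEEN"
  expect_equal(predict(fit, new1), predict(fit, new2))  # no individual offset
  extreme <- data.frame(participant_id = "UNSEEN", last_phq8 = 200, feat = 50)
  expect_lte(predict(fit, extreme), 24)
  expect_gte(predict(fit, data.frame(participant_id = "UNSEEN",
                                     last_phq8 = -200, feat = -50)), 0)
})

test_that("pooled metrics follow their definitions", {
  y <- c(3, 7, 11, 15)
  perfect <- evaluate_predictions(y, y)
  expect_equal(perfect$r2, 1)
  expect_equal(perfect$rmse, 0)
  at_mean <- evaluate_predictions(rep(mean(y), 4), y)
  expect_equal(at_mean$r2, 0)
  worse <- evaluate_predictions(c(20, 0, 20, 0), y)
  expect_lt(worse$r2, 0)
  expect_error(evaluate_predictions(1:3, 1:4), "length")
  one <- evaluate_predictions(5, 6)
  expect_true(is.na(one$r2))
  expect_equal(one$n_test, 1)
})

test_that("the baseline model uses exactly four predictors", {
  d <- make_hier_linear(seed = 77, J = 20, t = 4)
  fit <- suppressWarnings(fit_hierarchical(
    d, c("age", "gender", "education_years"),
    hier_spec(draws = 200, warmup = 200, chains = 2, seed = 2)))
  expect_setequal(fit$predictor_names,
                  c("last_phq8", "age", "gender", "education_years"))
  expect_length(fit$predictor_names, 4)
})

test_that("baseline prediction tracks autocorrelated outcomes under LAO", {
  # outcome driven almost entirely by the last observed score
  set.seed(78)
  iv <- make_interval_table(counts = rep(6, 25))
  iv$phq8_score <- NA_real_
  for (pid in unique(iv$participant_id)) {
    sel <- iv$participant_id == pid
    s <- numeric(6); s[1] <- runif(1, 4, 20)
    for (t in 2:6) s[t] <- 0.9 * s[t - 1] + rnorm(1, 0.5, 1)
    iv$phq8_score[sel] <- round(pmin(24, pmax(0, s)))
  }
  iv$age <- 50; iv$gender <- "female"; iv$education_years <- 16
  # ensure the range-5 criterion holds for most participants
  cv <- suppressWarnings(run_cv(iv, "lao", "baseline",
                                hier_spec(draws = 200, warmup = 200,
                                          chains = 2, seed = 3)))
  expect_gt(cv$metrics$r2, 0)
})

test_that("null severity coupling gives the full model no real edge", {
  diffs <- vapply(1:5, function(s) {
    cfg <- cohort_config(n_participants = 40, followup_days = 84,
                         severity_coupling = list(amount = 0, variance = 0,
                                                  amplitude = 0,
                                                  irregularity = 0),
                         seed = 500 + s)
    co <- generate_cohort(cfg)
    iv <- build_intervals(co$scans, co$phq8, co$demographics)
    ft <- extract_feature_table(iv, co$demographics)
    sp <- hier_spec(draws = 250, warmup = 250, chains = 2, seed = s)
    full <- suppressWarnings(run_cv(ft, "lao", "full", sp))
    base <- suppressWarnings(run_cv(ft, "lao", "baseline", sp))
    full$metrics$r2 - base$metrics$r2
  }, 0)
  # features carry no information, so any advantage is sampling noise
  expect_lt(mean(diffs), 0.05)
})
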