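# Hierarchical Bayesian prediction of PHQ-8 scores and the two time-series
# cross-validation schemes (leave-all-out and leave-one-out).

#' Select the prediction subset of participants
#'
#' Keeps participants with at least `min_intervals` retained intervals and a
#' within-participant PHQ-8 range of at least `min_range` (a clinically
#' meaningful change), so every participant supports time-series
#' cross-validation and shows predictable variability.
#'
#' @param intervals data.frame with `participant_id`, `questionnaire_date`
#'   and `phq8_score` (e.g. the `intervals` element of [build_intervals()] or
#'   a feature table).
#' @param min_intervals minimum interval count (default 3).
#' @param min_range minimum score range (default 5).
#' @return the input rows restricted to the selected participants, ordered by
#'   participant and date.
#' @export
select_prediction_subset <- function(intervals, min_intervals = 3,
                                     min_range = 5) {
  sp <- split(intervals, intervals$participant_id)
  keep <- names(sp)[vapply(sp, function(d)
    nrow(d) >= min_intervals &&
      (max(d$phq8_score) - min(d$phq8_score)) >= min_range, logical(1))]
  out <- intervals[intervals$participant_id %in% keep, , drop = FALSE]
  out[order(out$participant_id, out$questionnaire_date), ]
}

.interval_rank <- function(df) {
  df <- df[order(df$participant_id, df$questionnaire_date), , drop = FALSE]
  if (anyNA(df$questionnaire_date))
    stop_validation("missing questionnaire dates")
  dup <- unlist(lapply(split(df$questionnaire_date, df$participant_id),
                       function(x) any(duplicated(x)) || is.unsorted(x)))
  if (any(dup))
    stop_validation("unordered or duplicated questionnaire dates for participant(s): %s",
                    paste(names(dup)[dup], collapse = ", "))
  df$.rank <- as.integer(stats::ave(as.numeric(df$questionnaire_date),
                                    df$participant_id, FUN = seq_along))
  df
}

#' Leave-all-out (rolling-origin) time-series CV plan
#'
#' Fold `k` (for `k = 2..T`, `T` the maximum interval count of any
#' participant) tests every participant's `k`-th interval and trains on those
#' participants' intervals `1..k-1`, pooled. Participants with fewer than `k`
#' intervals do not contribute to fold `k`. The first interval is never
#' tested (no prior data), giving `T - 1` folds.
#'
#' @param subset data.frame from [select_prediction_subset()] with
#'   `interval_id`, `participant_id`, `questionnaire_date`.
#' @return list of class `cv_plan` with `scheme`, `folds` (each holding
#'   `train` and `test` interval ids), `T`, `J`.
#' @export
lao_splits <- function(subset) {
  if (nrow(subset) == 0L) stop_validation("empty prediction subset")
  d <- .interval_rank(subset)
  T_max <- max(d$.rank)
  folds <- lapply(2:T_max, function(k) {
    test_pids <- d$participant_id[d$.rank == k]
    list(train = d$interval_id[d$participant_id %in% test_pids & d$.rank < k],
         test = d$interval_id[d$.rank == k])
  })
  structure(list(scheme = "LAO", folds = folds, T = T_max,
                 J = length(unique(d$participant_id))),
            class = "cv_plan")
}

#' Leave-one-out time-series CV plan
#'
#' One fold per participant: the training set is that participant's first two
#' intervals pooled with all intervals of every other participant; the test
#' set is the participant's remaining intervals (3rd onward). Every subset
#' participant must have at least 3 intervals.
#'
#' @inheritParams lao_splits
#' @return a `cv_plan` with `J` folds.
#' @export
loo_splits <- function(subset) {
  if (nrow(subset) == 0L) stop_validation("empty prediction subset")
  d <- .interval_rank(subset)
  counts <- table(d$participant_id)
  if (any(counts < 3))
    stop_runtime("participant(s) with < 3 intervals in LOO subset: %s",
                 paste(names(counts)[counts < 3], collapse = ", "))
  pids <- sort(unique(d$participant_id))
  folds <- lapply(pids, function(pid) {
    own <- d$participant_id == pid
    list(train = d$interval_id[(!own) | (own & d$.rank <= 2)],
         test = d$interval_id[own & d$.rank >= 3])
  })
  structure(list(scheme = "LOO", folds = folds, T = max(d$.rank),
                 J = length(pids)), class = "cv_plan")
}

#' @export
print.cv_plan <- function(x, ...) {
  cat(sprintf("<cv_plan> %s: %d fold(s), J = %d participants, T = %d\n",
              x$scheme, length(x$folds), x$J, x$T))
  invisible(x)
}

#' Audit a CV plan for temporal leakage
#'
#' Verifies that within every fold, for each participant appearing in the
#' test set, every training interval of that participant predates every test
#' interval.
#'
#' @param plan a `cv_plan`.
#' @param subset the interval table the plan was built from.
#' @return `TRUE` invisibly; errors if any fold leaks future data.
#' @export
audit_cv_plan <- function(plan, subset) {
  stopifnot(inherits(plan, "cv_plan"))
  d <- subset[order(subset$participant_id, subset$questionnaire_date), ]
  date_of <- stats::setNames(as.numeric(d$questionnaire_date), d$interval_id)
  pid_of <- stats::setNames(d$participant_id, d$interval_id)
  for (i in seq_along(plan$folds)) {
    f <- plan$folds[[i]]
    for (pid in unique(pid_of[f$test])) {
      tr <- f$train[pid_of[f$train] == pid]
      te <- f$test[pid_of[f$test] == pid]
      if (length(tr) && max(date_of[tr]) >= min(date_of[te]))
        stop_runtime("temporal leakage in fold %d for participant %s", i, pid)
    }
  }
  invisible(TRUE)
}

#' Sampler / model settings for the hierarchical fit
#'
#' @param draws post-warmup draws per chain.
#' @param warmup warmup (tuning) iterations per chain, discarded.
#' @param chains number of chains.
#' @param seed RNG seed, recorded in the fit.
#' @param prior_slope_sd prior sd of population slopes on the standardized
#'   scale (default 1, a regularizing shrinkage prior).
#' @param prior_tau_sd half-normal prior scale for the hierarchy sds.
#' @param prior_sigma_sd half-normal prior scale for the noise sd, in PHQ-8
#'   score units (default 5).
#' @return list of class `hier_spec`.
#' @export
hier_spec <- function(draws = 1000, warmup = 1000, chains = 4, seed = 1L,
                      prior_slope_sd = 1, prior_tau_sd = 1,
                      prior_sigma_sd = 5) {
  stopifnot(draws >= 10, warmup >= 10, chains >= 1)
  structure(list(draws = as.integer(draws), warmup = as.integer(warmup),
                 chains = as.integer(chains), seed = as.integer(seed),
                 prior_slope_sd = prior_slope_sd, prior_tau_sd = prior_tau_sd,
                 prior_sigma_sd = prior_sigma_sd),
            class = "hier_spec")
}

# Build the population design matrix (standardized) for the hierarchical
# model: feature / demographic columns; gender becomes a binary indicator.
.design <- function(data, predictors, scalers = NULL) {
  X <- matrix(0, nrow(data), length(predictors),
              dimnames = list(NULL, predictors))
  for (p in predictors) {
    v <- data[[p]]
    if (is.null(v)) stop_validation("unknown predictor column: %s", p)
    if (p == "gender") v <- as.numeric(v == "male")
    X[, p] <- as.numeric(v)
  }
  if (is.null(scalers)) {
    center <- colMeans(X)
    scale <- apply(X, 2, stats::sd)
    scale[!is.finite(scale) | scale == 0] <- 1
  } else {
    center <- scalers$center; scale <- scalers$scale
  }
  list(X = sweep(sweep(X, 2, center), 2, scale, "/"),
       center = center, scale = scale)
}

#' Fit the hierarchical Bayesian linear regression
#'
#' Model (on standardized response and predictors): per-participant intercept
#' `alpha_j` and per-participant slope `b_j` on the last observed PHQ-8
#' score, both partially pooled through population means and half-normal
#' hierarchy scales; population-level slopes `beta` on the remaining
#' predictors with independent Normal(0, `prior_slope_sd`) shrinkage priors;
#' Gaussian noise with a half-normal prior on its sd (expressed in score
#' units). Sampling is by Gibbs updates — all conditionals are conjugate
#' normals except the scale parameters, which use slice updates on the log
#' scale. Split-Rhat over chains is reported for the population parameters.
#'
#' @param train data.frame with `phq8_score`, `participant_id`, `last_phq8`
#'   and every predictor column.
#' @param predictors population-level predictor names (features and
#'   demographics; `last_phq8` is always included through the hierarchical
#'   slope and must not be listed here).
#' @param spec a [hier_spec()].
#' @return object of class `nbdc_hier_fit` holding posterior means,
#'   population-parameter draws, participant effect estimates, scalers and
#'   diagnostics.
#' @export
fit_hierarchical <- function(train, predictors, spec = hier_spec()) {
  stopifnot(inherits(spec, "hier_spec"))
  if (nrow(train) == 0L) stop_validation("empty training set")
  if ("last_phq8" %in% predictors)
    stop_validation("last_phq8 is modelled hierarchically; do not list it as a population predictor")
  if (length(unique(train$participant_id)) < 2L)
    stop_validation("need at least 2 participants to fit the hierarchy")
  ys <- standardize(as.numeric(train$phq8_score))
  y <- ys$x
  ls <- standardize(as.numeric(train$last_phq8))
  l <- ls$x
  des <- .design(train, predictors)
  X <- des$X
  g <- match(train$participant_id, sort(unique(train$participant_id)))
  J <- max(g)
  n <- length(y)
  p <- ncol(X)
  sigma_prior <- spec$prior_sigma_sd / ys$scale  # score units -> std scale
  XtX <- crossprod(X)
  prior_prec_beta <- diag(1 / spec$prior_slope_sd^2, p)
  n_j <- tabulate(g, J)
  l2_j <- as.numeric(rowsum(l^2, g))

  hn_lp <- function(s, scale) -s^2 / (2 * scale^2)  # half-normal log kernel
  run_chain <- function(chain_seed) {
    set.seed(chain_seed)
    beta <- rep(0, p); alpha <- rep(0, J); b <- rep(0, J)
    mu_a <- 0; mu_b <- 0; tau_a <- 0.5; tau_b <- 0.5; sigma <- 1
    iters <- spec$warmup + spec$draws
    pop <- matrix(NA_real_, spec$draws, p + 5,
                  dimnames = list(NULL, c(colnames(X), "mu_alpha", "mu_b",
                                          "tau_alpha", "tau_b", "sigma")))
    alpha_sum <- numeric(J); b_sum <- numeric(J)
    for (it in seq_len(iters)) {
      # beta | rest
      r <- y - alpha[g] - b[g] * l
      A <- XtX / sigma^2 + prior_prec_beta
      ch <- chol(A)
      mean_beta <- backsolve(ch, forwardsolve(t(ch), crossprod(X, r) / sigma^2))
      beta <- as.numeric(mean_beta + backsolve(ch, stats::rnorm(p)))
      xb <- as.numeric(X %*% beta)
      # alpha_j | rest
      r <- y - xb - b[g] * l
      prec <- n_j / sigma^2 + 1 / tau_a^2
      mu_post <- (as.numeric(rowsum(r, g)) / sigma^2 + mu_a / tau_a^2) / prec
      alpha <- stats::rnorm(J, mu_post, sqrt(1 / prec))
      # b_j | rest
      r <- y - xb - alpha[g]
      prec <- l2_j / sigma^2 + 1 / tau_b^2
      mu_post <- (as.numeric(rowsum(r * l, g)) / sigma^2 + mu_b / tau_b^2) / prec
      b <- stats::rnorm(J, mu_post, sqrt(1 / prec))
      # population means (Normal(0,1) hyperpriors on the standardized scale)
      prec <- J / tau_a^2 + 1
      mu_a <- stats::rnorm(1, sum(alpha) / tau_a^2 / prec, sqrt(1 / prec))
      prec <- J / tau_b^2 + 1
      mu_b <- stats::rnorm(1, sum(b) / tau_b^2 / prec, sqrt(1 / prec))
      # hierarchy scales: slice on log(tau), half-normal priors
      ssa <- sum((alpha - mu_a)^2)
      tau_a <- exp(slice_sample1(log(tau_a), function(lt) {
        t <- exp(lt)
        -J * lt - ssa / (2 * t^2) + hn_lp(t, spec$prior_tau_sd) + lt
      }))
      ssb <- sum((b - mu_b)^2)
      tau_b <- exp(slice_sample1(log(tau_b), function(lt) {
        t <- exp(lt)
        -J * lt - ssb / (2 * t^2) + hn_lp(t, spec$prior_tau_sd) + lt
      }))
      # interweaving (ASIS): resample each hierarchy scale in the
      # non-centered parameterization to break the funnel between the
      # scale and its group effects
      resid_a <- y - xb - mu_a - b[g] * l
      a_til <- (alpha - mu_a) / tau_a
      w <- a_til[g]
      prec <- sum(w^2) / sigma^2 + 1 / spec$prior_tau_sd^2
      t_new <- stats::rnorm(1, sum(w * resid_a) / sigma^2 / prec, sqrt(1 / prec))
      tau_a <- max(abs(t_new), 1e-8)
      alpha <- mu_a + t_new * a_til
      resid_b <- y - xb - alpha[g] - mu_b * l
      b_til <- (b - mu_b) / tau_b
      w <- b_til[g] * l
      prec <- sum(w^2) / sigma^2 + 1 / spec$prior_tau_sd^2
      t_new <- stats::rnorm(1, sum(w * resid_b) / sigma^2 / prec, sqrt(1 / prec))
      tau_b <- max(abs(t_new), 1e-8)
      b <- mu_b + t_new * b_til
      # noise sd: slice on log(sigma), half-normal prior (score units)
      ssr <- sum((y - xb - alpha[g] - b[g] * l)^2)
      sigma <- exp(slice_sample1(log(sigma), function(ls_) {
        s <- exp(ls_)
        -n * ls_ - ssr / (2 * s^2) + hn_lp(s, sigma_prior) + ls_
      }))
      if (it > spec$warmup) {
        d_i <- it - spec$warmup
        pop[d_i, ] <- c(beta, mu_a, mu_b, tau_a, tau_b, sigma)
        alpha_sum <- alpha_sum + alpha
        b_sum <- b_sum + b
      }
    }
    list(pop = pop, alpha_mean = alpha_sum / spec$draws,
         b_mean = b_sum / spec$draws)
  }

  chains <- lapply(seq_len(spec$chains), function(cc)
    run_chain(spec$seed + 1000L * (cc - 1L)))
  pop_all <- do.call(rbind, lapply(chains, `[[`, "pop"))
  rhat <- vapply(seq_len(ncol(pop_all)), function(j)
    split_rhat(sapply(chains, function(cc) cc$pop[, j])), 0)
  names(rhat) <- colnames(pop_all)
  if (spec$chains >= 2L) {
    bad <- names(rhat)[is.finite(rhat) & rhat > 1.05]
    if (length(bad))
      warning(sprintf("population parameter(s) with split-Rhat > 1.05: %s",
                      paste(bad, collapse = ", ")), call. = FALSE)
  }
  alpha_mean <- rowMeans(sapply(chains, `[[`, "alpha_mean"))
  b_mean <- rowMeans(sapply(chains, `[[`, "b_mean"))
  pop_mean <- colMeans(pop_all)
  structure(list(
    predictors = predictors,
    predictor_names = c("last_phq8", predictors),
    pop_draws = pop_all,
    pop_mean = pop_mean,
    beta_mean = pop_mean[seq_len(p)],
    alpha_mean = alpha_mean, b_mean = b_mean,
    participants = sort(unique(train$participant_id)),
    scalers = list(y = ys[c("center", "scale")],
                   last = ls[c("center", "scale")],
                   X = des[c("center", "scale")]),
    rhat = rhat, spec = spec, n_train = n, J = J),
    class = "nbdc_hier_fit")
}

#' Posterior-mean slope summary on the raw predictor scale
#'
#' @param fit an `nbdc_hier_fit`.
#' @param prob central credible-interval mass (default 0.95).
#' @return data.frame with posterior mean, sd and interval bounds per
#'   population slope, both standardized and in raw score-per-unit terms.
#' @export
coef_summary <- function(fit, prob = 0.95) {
  stopifnot(inherits(fit, "nbdc_hier_fit"))
  p <- length(fit$predictors)
  draws <- fit$pop_draws[, seq_len(p), drop = FALSE]
  a <- (1 - prob) / 2
  raw_scale <- fit$scalers$y$scale / fit$scalers$X$scale
  data.frame(
    predictor = fit$predictors,
    mean_std = colMeans(draws),
    sd_std = apply(draws, 2, stats::sd),
    mean_raw = colMeans(draws) * raw_scale,
    lower_raw = apply(draws, 2, stats::quantile, a) * raw_scale,
    upper_raw = apply(draws, 2, stats::quantile, 1 - a) * raw_scale,
    row.names = NULL)
}

#' Predict PHQ-8 scores from a hierarchical fit
#'
#' Posterior-mean point predictions. Participants seen in training use their
#' posterior-mean intercept and last-score slope; unseen participants fall
#' back on the population means. Predictors are standardized with the
#' training statistics and predictions are clipped to the 0-24 score range.
#'
#' @param object an `nbdc_hier_fit`.
#' @param newdata data.frame with `participant_id`, `last_phq8` and the
#'   predictor columns.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.nbdc_hier_fit <- function(object, newdata, ...) {
  des <- .design(newdata, object$predictors, object$scalers$X)
  l <- (as.numeric(newdata$last_phq8) - object$scalers$last$center) /
    object$scalers$last$scale
  idx <- match(newdata$participant_id, object$participants)
  pm <- object$pop_mean
  alpha <- ifelse(is.na(idx), pm[["mu_alpha"]], object$alpha_mean[idx])
  b <- ifelse(is.na(idx), pm[["mu_b"]], object$b_mean[idx])
  yhat_std <- alpha + b * l + as.numeric(des$X %*% object$beta_mean)
  yhat <- object$scalers$y$center + object$scalers$y$scale * yhat_std
  pmin(24, pmax(0, yhat))
}

#' Pooled prediction metrics
#'
#' @param predictions,truths equal-length numeric vectors pooled over all
#'   folds of a CV plan.
#' @return list with `r2` (predicted coefficient of determination about the
#'   pooled test mean; can be negative, `NA` when fewer than 2 test points),
#'   `rmse` (score units) and `n_test`.
#' @export
evaluate_predictions <- function(predictions, truths) {
  if (length(predictions) != length(truths))
    stop_validation("predictions and truths differ in length (%d vs %d)",
                    length(predictions), length(truths))
  n <- length(truths)
  rmse <- sqrt(mean((predictions - truths)^2))
  ss_tot <- sum((truths - mean(truths))^2)
  r2 <- if (n < 2L || ss_tot == 0) NA_real_
        else 1 - sum((truths - predictions)^2) / ss_tot
  list(r2 = r2, rmse = rmse, n_test = n)
}

#' Add the last-observed-PHQ-8 predictor
#'
#' For each interval, the participant's most recent earlier retained score.
#' First intervals have no predecessor and are imputed with the participant's
#' own first observed score (they only ever appear as training rows — both CV
#' schemes start testing at the second interval or later).
#'
#' @param feature_table data.frame with `participant_id`,
#'   `questionnaire_date`, `phq8_score`.
#' @return the table with a `last_phq8` column, ordered by participant/date.
#' @export
add_last_phq8 <- function(feature_table) {
  d <- feature_table[order(feature_table$participant_id,
                           feature_table$questionnaire_date), , drop = FALSE]
  d$last_phq8 <- stats::ave(as.numeric(d$phq8_score), d$participant_id,
                            FUN = function(x) c(x[1], x[-length(x)]))
  d
}

#' Run one model under one CV scheme
#'
#' Builds the plan, audits it for temporal leakage, fits the hierarchical
#' model per fold and pools predictions across folds into a single R2/RMSE
#' pair (the single-number-per-scheme convention).
#'
#' @param feature_table feature table restricted or not; subset selection is
#'   applied internally via [select_prediction_subset()].
#' @param scheme `"lao"` or `"loo"`.
#' @param model `"full"` (49 features + demographics + last score) or
#'   `"baseline"` (demographics + last score only).
#' @param spec a [hier_spec()].
#' @param entropy an [entropy_config()] naming the feature columns.
#' @param min_intervals,min_range subset criteria.
#' @return list with the `plan`, per-row `predictions` data.frame and pooled
#'   `metrics`.
#' @export
run_cv <- function(feature_table, scheme = c("lao", "loo"),
                   model = c("full", "baseline"), spec = hier_spec(),
                   entropy = entropy_config(),
                   min_intervals = 3, min_range = 5) {
  scheme <- match.arg(scheme)
  model <- match.arg(model)
  subset <- select_prediction_subset(feature_table, min_intervals, min_range)
  if (nrow(subset) == 0L)
    stop_validation("no participants satisfy the prediction subset criteria")
  subset <- add_last_phq8(subset)
  plan <- if (scheme == "lao") lao_splits(subset) else loo_splits(subset)
  audit_cv_plan(plan, subset)
  demo <- c("age", "gender", "education_years")
  predictors <- if (model == "full")
    c(intersect(feature_names(entropy), names(subset)), demo) else demo
  rows <- stats::setNames(seq_len(nrow(subset)), subset$interval_id)
  preds <- vector("list", length(plan$folds))
  for (k in seq_along(plan$folds)) {
    f <- plan$folds[[k]]
    train <- subset[rows[f$train], , drop = FALSE]
    test <- subset[rows[f$test], , drop = FALSE]
    fit <- fit_hierarchical(train, predictors, spec)
    preds[[k]] <- data.frame(fold = k, interval_id = test$interval_id,
                             participant_id = test$participant_id,
                             truth = test$phq8_score,
                             prediction = predict(fit, test))
  }
  predictions <- do.call(rbind, preds)
  metrics <- evaluate_predictions(predictions$prediction, predictions$truth)
  list(plan = plan, predictions = predictions,
       metrics = c(metrics, list(scheme = toupper(scheme), model = model)))
}
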