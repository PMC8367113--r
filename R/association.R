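# Association screening: pairwise linear mixed-effects models per feature,
# Benjamini-Hochberg correction, and the nested-model likelihood-ratio ladder.

.covariate_rhs <- function(covariates) paste(covariates, collapse = " + ")

#' Pairwise linear mixed-effects association for one feature
#'
#' Regresses the PHQ-8 score on a single Bluetooth feature with a random
#' participant intercept and the baseline covariates (age, gender, years in
#' education) as fixed effects. Significance uses the z-test on the feature
#' coefficient. The feature is z-standardized before fitting for numerical
#' comparability; the estimate and its standard error are reported on the
#' raw feature scale (and the standardized scale alongside).
#'
#' @param data data.frame holding `phq8_score`, `participant_id`, the
#'   covariates and the feature column.
#' @param feature name of the feature column.
#' @param covariates fixed-effect covariate names.
#' @param reml fit by REML (default, as usual for single-model screening).
#' @return one-row data.frame: `feature_name`, `estimate`, `se`, `z`,
#'   `p_raw` on the raw feature scale, `estimate_std`, `se_std` on the
#'   standardized scale, and a logical `flagged` (degenerate or singular
#'   fits are flagged and carry `NA` statistics).
#' @export
pairwise_lmm <- function(data, feature,
                         covariates = c("age", "gender", "education_years"),
                         reml = TRUE) {
  stopifnot(feature %in% names(data))
  miss <- setdiff(c("phq8_score", "participant_id", covariates), names(data))
  if (length(miss)) stop_validation("missing columns: %s", paste(miss, collapse = ", "))
  flagged_row <- function(note) data.frame(
    feature_name = feature, estimate = NA_real_, se = NA_real_, z = NA_real_,
    p_raw = NA_real_, estimate_std = NA_real_, se_std = NA_real_,
    flagged = TRUE, note = note)
  x <- data[[feature]]
  if (anyNA(x)) return(flagged_row("missing feature values"))
  sx <- stats::sd(x)
  if (!is.finite(sx) || sx == 0) return(flagged_row("constant feature"))
  d <- data
  d$.feat <- (x - mean(x)) / sx
  f <- stats::as.formula(paste("phq8_score ~ .feat +", .covariate_rhs(covariates),
                               "+ (1 | participant_id)"))
  fit <- tryCatch(lme4::lmer(f, data = d, REML = reml),
                  error = function(e) NULL)
  if (is.null(fit)) return(flagged_row("fit failed"))
  singular <- lme4::isSingular(fit)
  co <- summary(fit)$coefficients
  est_std <- co[".feat", "Estimate"]
  se_std <- co[".feat", "Std. Error"]
  z <- est_std / se_std
  data.frame(feature_name = feature,
             estimate = est_std / sx, se = se_std / sx, z = z,
             p_raw = 2 * stats::pnorm(-abs(z)),
             estimate_std = est_std, se_std = se_std,
             flagged = singular,
             note = if (singular) "singular fit" else "")
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin validating wrapper around `p.adjust(..., method = "BH")`: monotone
#' step-up adjusted values capped at 1, invariant to input order.
#'
#' @param p numeric vector of raw p values in `[0, 1]`.
#' @return adjusted p values in the input order.
#' @export
bh_adjust <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1))
    stop_validation("p values must lie in [0, 1] with no missing values")
  stats::p.adjust(p, method = "BH")
}

#' Screen every feature against the PHQ-8 score
#'
#' Runs [pairwise_lmm()] for each feature and applies Benjamini-Hochberg
#' adjustment across the non-flagged fits; flagged features are excluded from
#' the adjustment and keep `NA` adjusted values.
#'
#' @param feature_table output of [extract_feature_table()] (or any
#'   data.frame with the same score/covariate columns).
#' @param features feature column names; default the 49 Bluetooth features.
#' @param covariates fixed-effect covariates.
#' @return data.frame with one row per feature including `p_adjusted`,
#'   ordered as supplied.
#' @export
associate_features <- function(feature_table,
                               features = intersect(feature_names(),
                                                    names(feature_table)),
                               covariates = c("age", "gender", "education_years")) {
  rows <- lapply(features, function(f)
    pairwise_lmm(feature_table, f, covariates))
  res <- do.call(rbind, rows)
  res$p_adjusted <- NA_real_
  ok <- !res$flagged & !is.na(res$p_raw)
  res$p_adjusted[ok] <- bh_adjust(res$p_raw[ok])
  rownames(res) <- NULL
  res
}

#' Fit the nested model ladder A/B/C
#'
#' Three nested linear mixed-effects models with random participant
#' intercepts, fitted by maximum likelihood (not REML) on identical rows so
#' likelihood-ratio tests between them are valid: model A has demographics
#' only; model B adds the 16 second-order statistical features; model C adds
#' all 49 Bluetooth features. Features are z-standardized before fitting.
#'
#' @param feature_table output of [extract_feature_table()].
#' @param covariates demographic covariates.
#' @param entropy an [entropy_config()] (defines the feature name sets).
#' @param drop_collinear by default exact collinearity among the features is
#'   an error naming the aliased columns. Real extracted features carry one
#'   built-in exact dependency — the three band fractions sum to 1 — and can
#'   contain constant columns (e.g. `Min_Min` when every daily minimum is 0),
#'   so `drop_collinear = TRUE` removes aliased columns (QR pivot order) and
#'   records them in the result; degrees of freedom then reflect the columns
#'   actually fitted.
#' @return list with fitted models `A`, `B`, `C`, the `n` common rows, the
#'   feature sets used and any `dropped` columns.
#' @export
fit_nested_models <- function(feature_table,
                              covariates = c("age", "gender", "education_years"),
                              entropy = entropy_config(),
                              drop_collinear = FALSE) {
  all_feats <- feature_names(entropy)
  so_feats <- all_feats[1:16]
  miss <- setdiff(c(all_feats, covariates, "phq8_score", "participant_id"),
                  names(feature_table))
  if (length(miss)) stop_validation("missing columns: %s", paste(miss, collapse = ", "))
  d <- feature_table[stats::complete.cases(
    feature_table[c(all_feats, covariates, "phq8_score")]), , drop = FALSE]
  for (f in all_feats) {
    s <- stats::sd(d[[f]])
    d[[f]] <- (d[[f]] - mean(d[[f]])) / if (is.finite(s) && s > 0) s else 1
  }
  mm <- stats::model.matrix(stats::as.formula(paste("~", paste(all_feats, collapse = "+"))), d)
  qr_rank <- qr(mm)
  dropped <- character()
  if (qr_rank$rank < ncol(mm)) {
    dropped <- colnames(mm)[qr_rank$pivot[(qr_rank$rank + 1):ncol(mm)]]
    if (!drop_collinear)
      stop_validation("rank-deficient feature matrix; collinear column(s): %s",
                      paste(dropped, collapse = ", "))
    all_feats <- setdiff(all_feats, dropped)
    so_feats <- setdiff(so_feats, dropped)
  }
  fit_one <- function(feats) {
    rhs <- paste(c(covariates, feats), collapse = " + ")
    lme4::lmer(stats::as.formula(
      paste("phq8_score ~", rhs, "+ (1 | participant_id)")),
      data = d, REML = FALSE)
  }
  list(A = fit_one(character()), B = fit_one(so_feats), C = fit_one(all_feats),
       n = nrow(d), second_order = so_feats, all_features = all_feats,
       dropped = dropped)
}

#' Likelihood-ratio test between two nested mixed models
#'
#' @param model_small,model_large `merMod` fits by maximum likelihood on the
#'   same rows; the fixed effects of the small model must be a subset of the
#'   large model's.
#' @param alpha significance level for the attached critical value.
#' @return one-row data.frame: `df_diff`, `chi2_stat`, `p`,
#'   `critical_value_05` (the upper-`alpha` chi-square quantile).
#' @export
likelihood_ratio_test <- function(model_small, model_large, alpha = 0.05) {
  fe_s <- names(lme4::fixef(model_small))
  fe_l <- names(lme4::fixef(model_large))
  if (!all(fe_s %in% fe_l))
    stop_validation("models are not nested: small-model terms %s absent from large model",
                    paste(setdiff(fe_s, fe_l), collapse = ", "))
  if (stats::nobs(model_small) != stats::nobs(model_large))
    stop_validation("models were fitted on different numbers of rows")
  if (isTRUE(lme4::isREML(model_small)) || isTRUE(lme4::isREML(model_large)))
    stop_validation("likelihood-ratio tests require maximum-likelihood fits")
  ll_s <- stats::logLik(model_small)
  ll_l <- stats::logLik(model_large)
  df_diff <- attr(ll_l, "df") - attr(ll_s, "df")
  stat <- max(0, 2 * (as.numeric(ll_l) - as.numeric(ll_s)))
  if (df_diff == 0L)   # identical parameter sets: nothing to test
    return(data.frame(df_diff = 0L, chi2_stat = stat, p = 1,
                      critical_value_05 = NA_real_))
  data.frame(df_diff = df_diff, chi2_stat = stat,
             p = stats::pchisq(stat, df_diff, lower.tail = FALSE),
             critical_value_05 = chi2_critical(df_diff, alpha))
}

#' Run the likelihood-ratio ladder B vs A, C vs A, C vs B
#'
#' @param nested result of [fit_nested_models()].
#' @return data.frame with one row per comparison.
#' @export
lrt_ladder <- function(nested) {
  pairs <- list(c("B", "A"), c("C", "A"), c("C", "B"))
  out <- do.call(rbind, lapply(pairs, function(p) {
    r <- likelihood_ratio_test(nested[[p[2]]], nested[[p[1]]])
    cbind(data.frame(model_pair = paste(p[1], "vs", p[2])), r)
  }))
  rownames(out) <- NULL
  out
}

#' Upper-tail chi-square critical value
#'
#' @param df degrees of freedom, `>= 1`.
#' @param alpha tail probability in (0, 1); default 0.05.
#' @return the upper-`alpha` quantile of the chi-square distribution.
#' @export
chi2_critical <- function(df, alpha = 0.05) {
  if (any(df < 1) || any(alpha <= 0 | alpha >= 1))
    stop_validation("need df >= 1 and alpha in (0, 1)")
  stats::qchisq(alpha, df = df, lower.tail = FALSE)
}
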