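# The 49 Bluetooth features: 16 second-order statistics of daily summaries,
# multiscale sample entropy at scales 1-24, and periodogram band powers,
# band fractions and spectral entropies in three cycles-per-day bands.

#' Entropy configuration
#'
#' @param m template (embedding) length for sample entropy; default 2, the
#'   standard choice for multiscale entropy.
#' @param r_fraction tolerance as a fraction of the scale-1 sequence standard
#'   deviation; default 0.2. The tolerance is fixed from the original
#'   sequence and held constant across scales.
#' @param max_scale largest coarse-graining scale, default 24 (one hour up to
#'   one day for hourly data).
#' @return list of class `entropy_config`.
#' @export
entropy_config <- function(m = 2, r_fraction = 0.2, max_scale = 24) {
  if (m < 1 || r_fraction <= 0 || max_scale < 1)
    stop_validation("need m >= 1, r_fraction > 0, max_scale >= 1")
  structure(list(m = as.integer(m), r_fraction = r_fraction,
                 max_scale = as.integer(max_scale)),
            class = "entropy_config")
}

#' Frequency bands in cycles per day
#'
#' Default bands: low frequency (0, 0.75], middle frequency (0.75, 1.25] —
#' the circadian band — and high frequency (1.25, Nyquist]. Bands are
#' half-open `(lo, hi]`, disjoint, and jointly cover (0, Nyquist].
#'
#' @param lf,mf,hf numeric length-2 band edges; `Inf` is truncated at the
#'   Nyquist frequency (12 cycles/day for hourly data).
#' @return list of class `spectrum_bands`.
#' @export
spectrum_bands <- function(lf = c(0, 0.75), mf = c(0.75, 1.25),
                           hf = c(1.25, Inf)) {
  b <- list(lf = lf, mf = mf, hf = hf)
  edges <- c(lf, mf, hf)
  if (any(vapply(b, length, 0L) != 2L) || lf[1] != 0 ||
      lf[2] != mf[1] || mf[2] != hf[1] || any(diff(edges) < 0))
    stop_validation("bands must be ordered, contiguous and start at 0")
  structure(b, class = "spectrum_bands")
}

#' Per-day summary statistics of an interval sequence
#'
#' @param sequence complete hourly sequence, length a multiple of 24.
#' @return matrix with one row per valid day and columns `max`, `min`,
#'   `mean`, `std` (population standard deviation).
#' @export
daily_statistics <- function(sequence) {
  n <- length(sequence)
  if (n == 0L || n %% 24L != 0L)
    stop_validation("sequence length must be a positive multiple of 24")
  if (anyNA(sequence)) stop_validation("sequence contains missing values")
  days <- matrix(sequence, nrow = 24L)
  cbind(max = apply(days, 2, max), min = apply(days, 2, min),
        mean = colMeans(days), std = apply(days, 2, sd_pop))
}

#' Second-order statistics of the daily summaries
#'
#' For each daily feature (max, min, mean, std) the max, min, mean and
#' population std across days are taken, named `[Second-order]_[Daily]`
#' (e.g. `Mean_Max` is the mean over days of the daily maximum).
#'
#' @param daily matrix from [daily_statistics()].
#' @return named numeric vector of 16 values.
#' @export
second_order_features <- function(daily) {
  if (is.null(dim(daily)) || nrow(daily) < 1L)
    stop_validation("need at least one daily summary row")
  ops <- c(Max = max, Min = min, Mean = mean, Std = sd_pop)
  out <- c()
  for (dfeat in c("Max", "Min", "Std", "Mean")) {
    col <- daily[, tolower(dfeat)]
    for (sfeat in names(ops))
      out[paste(sfeat, dfeat, sep = "_")] <- ops[[sfeat]](col)
  }
  out
}

#' Coarse-grain a sequence
#'
#' Averages consecutive non-overlapping blocks of length `tau`; a trailing
#' remainder shorter than `tau` is dropped.
#'
#' @param sequence numeric vector.
#' @param tau block length (scale), `1 <= tau <= length(sequence)`.
#' @return numeric vector of length `floor(N / tau)`.
#' @export
coarse_grain <- function(sequence, tau) {
  n <- length(sequence)
  if (tau < 1 || tau != round(tau)) stop_validation("tau must be a positive integer")
  if (tau > n) stop_validation("tau (%d) exceeds sequence length (%d)", tau, n)
  if (tau == 1) return(sequence)
  nb <- n %/% tau
  colMeans(matrix(sequence[seq_len(nb * tau)], nrow = tau))
}

#' Sample entropy
#'
#' `-ln(A/B)` where `B` counts pairs of length-`m` templates within Chebyshev
#' distance `r` and `A` the same for length-`m+1` templates; templates are
#' taken at the first `N - m` positions for both counts and self-matches are
#' excluded. When either count is zero the Richman-Moorman upper bound
#' `-ln(2 / ((N-m)(N-m-1)))` is returned so the statistic stays finite.
#'
#' @param sequence numeric vector, length at least `m + 2`.
#' @param m template length.
#' @param r tolerance (same units as the sequence), `> =  0`.
#' @return non-negative scalar.
#' @export
sample_entropy <- function(sequence, m = 2, r) {
  n <- length(sequence)
  if (n < m + 2) stop_validation("sequence shorter than m + 2 (%d < %d)", n, m + 2)
  if (r < 0) stop_validation("tolerance r must be >= 0")
  nt <- n - m              # number of templates used for both counts
  d <- abs(outer(sequence, sequence, "-"))
  dm <- d[seq_len(nt), seq_len(nt), drop = FALSE]
  if (m > 1) for (k in seq_len(m - 1))
    dm <- pmax(dm, d[seq_len(nt) + k, seq_len(nt) + k, drop = FALSE])
  dm1 <- pmax(dm, d[seq_len(nt) + m, seq_len(nt) + m, drop = FALSE])
  B <- (sum(dm <= r) - nt) / 2
  A <- (sum(dm1 <= r) - nt) / 2
  if (A == 0 || B == 0) return(-log(2 / (nt * (nt - 1))))
  -log(A / B)
}

#' Multiscale sample entropy
#'
#' Sample entropy of the coarse-grained sequence at every scale `1..max_scale`
#' with the tolerance fixed at `r_fraction` times the standard deviation of
#' the original (scale-1) sequence.
#'
#' @param sequence complete numeric sequence; must support the largest scale
#'   (`length >= max_scale * (m + 2)`).
#' @param config an [entropy_config()].
#' @return named numeric vector `MSE_1 .. MSE_<max_scale>`.
#' @export
multiscale_entropy <- function(sequence, config = entropy_config()) {
  stopifnot(inherits(config, "entropy_config"))
  if (length(sequence) < config$max_scale * (config$m + 2))
    stop_validation("sequence too short for scale %d", config$max_scale)
  r <- config$r_fraction * stats::sd(sequence)
  vals <- vapply(seq_len(config$max_scale), function(tau)
    sample_entropy(coarse_grain(sequence, tau), config$m, r), 0)
  stats::setNames(vals, paste0("MSE_", seq_len(config$max_scale)))
}

#' One-sided periodogram in cycles per day
#'
#' Squared DFT magnitude divided by N, one-sided with interior bins doubled;
#' with hourly sampling the frequency axis is scaled to cycles per day
#' (Nyquist at 12). The DC bin is reported separately and excluded from the
#' band features, so the total reported power equals `N` times the population
#' variance of the sequence (Parseval).
#'
#' @param sequence complete numeric sequence, length at least 48 (two days).
#' @return list of class `nbdc_spectrum` with `freq` (cycles/day), `power`,
#'   `dc_power`, `total_power` (non-DC) and `n`.
#' @export
power_spectrum <- function(sequence) {
  n <- length(sequence)
  if (n < 48L) stop_validation("need at least 48 hourly values, got %d", n)
  if (anyNA(sequence)) stop_validation("sequence contains missing values")
  ft <- stats::fft(sequence)
  half <- n %/% 2L
  k <- seq_len(half)
  power <- Mod(ft[k + 1L])^2 / n
  dbl <- if (n %% 2L == 0L) k < half else k <= half   # Nyquist bin not doubled
  power[dbl] <- 2 * power[dbl]
  # clamp floating-point dust (e.g. the FFT of a constant) to exact zero
  power[power <= sum(sequence^2) * 1e-14] <- 0
  structure(list(freq = k / n * 24, power = power,
                 dc_power = Mod(ft[1L])^2 / n,
                 total_power = sum(power), n = n),
            class = "nbdc_spectrum")
}

#' Band power sums, fractions and spectral entropies
#'
#' For each band: the sum of periodogram power, its fraction of the total
#' non-DC power, and the Shannon entropy of the within-band normalized power
#' divided by `log(#bins in band)` so it lies in `[0, 1]` (1 = flat band,
#' no dominant rhythm). With zero total power the fractions and entropies are
#' undefined and returned as `NA`.
#'
#' @param spectrum an `nbdc_spectrum` from [power_spectrum()].
#' @param bands a [spectrum_bands()].
#' @return named numeric vector of 9 values: `LF_sum`, `MF_sum`, `HF_sum`,
#'   `LF_pct`, `MF_pct`, `HF_pct`, `LF_se`, `MF_se`, `HF_se`.
#' @export
band_features <- function(spectrum, bands = spectrum_bands()) {
  stopifnot(inherits(spectrum, "nbdc_spectrum"), inherits(bands, "spectrum_bands"))
  nyq <- max(spectrum$freq)
  out <- c()
  total <- spectrum$total_power
  for (nm in c("lf", "mf", "hf")) {
    lo <- bands[[nm]][1]; hi <- min(bands[[nm]][2], nyq)
    sel <- spectrum$freq > lo & spectrum$freq <= hi
    if (!any(sel))
      stop_validation("band %s contains no spectral bins", toupper(nm))
    p <- spectrum$power[sel]
    psum <- sum(p)
    lab <- toupper(nm)
    out[paste0(lab, "_sum")] <- psum
    out[paste0(lab, "_pct")] <- if (total > 0) psum / total else NA_real_
    if (psum > 0 && length(p) > 1L) {
      q <- p / psum
      q <- q[q > 0]
      out[paste0(lab, "_se")] <- -sum(q * log(q)) / log(length(p))
    } else if (psum > 0) {
      out[paste0(lab, "_se")] <- 0   # single-bin band: fully concentrated
    } else {
      out[paste0(lab, "_se")] <- NA_real_
    }
  }
  ord <- c(t(outer(c("sum", "pct", "se"), c("LF", "MF", "HF"),
                   function(s, b) paste0(b, "_", s))))
  out[ord]
}

#' Names of the 49 Bluetooth features, in stable order
#' @param config an [entropy_config()] (sets the number of MSE scales).
#' @return character vector of feature names.
#' @export
feature_names <- function(config = entropy_config()) {
  so <- c(t(outer(c("Max", "Min", "Std", "Mean"), c("Max", "Min", "Mean", "Std"),
                  function(d, s) paste(s, d, sep = "_"))))
  c(so, paste0("MSE_", seq_len(config$max_scale)),
    c("LF_sum", "MF_sum", "HF_sum", "LF_pct", "MF_pct", "HF_pct",
      "LF_se", "MF_se", "HF_se"))
}

#' Extract the 49 Bluetooth features from one interval sequence
#'
#' @param sequence complete hourly sequence of a retained interval (length a
#'   multiple of 24, at least 10 days).
#' @param entropy an [entropy_config()].
#' @param bands a [spectrum_bands()].
#' @return named numeric vector with the 49 features in the order of
#'   [feature_names()].
#' @export
extract_features <- function(sequence, entropy = entropy_config(),
                             bands = spectrum_bands()) {
  so <- second_order_features(daily_statistics(sequence))
  mse <- multiscale_entropy(sequence, entropy)
  fd <- band_features(power_spectrum(sequence), bands)
  out <- c(so, mse, fd)
  out[feature_names(entropy)]
}

#' Feature table for a set of intervals
#'
#' One row per retained interval: identifiers, the PHQ-8 score and severity
#' level, demographic covariates, and the 49 feature columns.
#'
#' @param intervals an `nbdc_intervals` object from [build_intervals()].
#' @param demographics data.frame with `participant_id`, `age`, `gender`,
#'   `education_years`.
#' @param entropy,bands feature configuration.
#' @return data.frame.
#' @export
extract_feature_table <- function(intervals, demographics,
                                  entropy = entropy_config(),
                                  bands = spectrum_bands()) {
  stopifnot(inherits(intervals, "nbdc_intervals"))
  meta <- intervals$intervals
  if (nrow(meta) == 0L) stop_validation("no retained intervals to featurize")
  feats <- t(vapply(meta$interval_id, function(iid)
    extract_features(intervals$sequences[[iid]], entropy, bands),
    numeric(length(feature_names(entropy)))))
  df <- cbind(meta[c("interval_id", "participant_id", "questionnaire_date",
                     "phq8_score", "severity_level", "valid_days")],
              as.data.frame(feats))
  out <- merge(df, demographics, by = "participant_id", sort = FALSE)
  out[order(out$participant_id, out$questionnaire_date), ]
}
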