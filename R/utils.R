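# Internal helpers shared across modules.

#' Signal a validation error
#'
#' Validation errors carry class `nbdc_validation_error` so callers (and the
#' command-line wrapper) can distinguish bad input from runtime failures.
#'
#' @param msg message, passed to [sprintf()] with `...`.
#' @param ... sprintf arguments.
#' @keywords internal
#' @noRd
stop_validation <- function(msg, ...) {
  stop(structure(
    class = c("nbdc_validation_error", "nbdc_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

#' @noRd
stop_runtime <- function(msg, ...) {
  stop(structure(
    class = c("nbdc_runtime_error", "nbdc_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

# Population (divide-by-n) standard deviation; the sequence over a day or the
# daily summaries over an interval are treated as the full population.
sd_pop <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_real_)
  sqrt(mean((x - mean(x))^2))
}

# Round half away from zero (0.5 -> 1), unlike base round()'s banker rounding;
# used when averaging multiple scans that fall in one clock-hour slot.
round_half_up <- function(x) floor(x + 0.5)

# Scale a vector to zero mean / unit sd; constant columns are centred only
# (sd set to 1 so downstream algebra stays finite).
standardize <- function(x, center = NULL, scale = NULL) {
  if (is.null(center)) center <- mean(x)
  if (is.null(scale)) scale <- stats::sd(x)
  if (!is.finite(scale) || scale == 0) scale <- 1
  list(x = (x - center) / scale, center = center, scale = scale)
}

# Univariate slice sampler (Neal 2003, stepping out + shrinkage) on an
# unbounded coordinate. Used for log-scale parameters with half-normal priors,
# whose full conditionals are not of standard form.
slice_sample1 <- function(x0, logpost, w = 1, max_steps = 50L) {
  f0 <- logpost(x0)
  if (!is.finite(f0)) stop_runtime("slice sampler started at zero-density point")
  logy <- f0 + log(stats::runif(1))
  u <- stats::runif(1)
  L <- x0 - w * u
  R <- L + w
  j <- floor(max_steps * stats::runif(1))
  k <- max_steps - 1L - j
  while (j > 0 && logpost(L) > logy) {
    L <- L - w
    j <- j - 1L
  }
  while (k > 0 && logpost(R) > logy) {
    R <- R + w
    k <- k - 1L
  }
  repeat {
    x1 <- stats::runif(1, L, R)
    if (logpost(x1) >= logy) return(x1)
    if (x1 < x0) L <- x1 else R <- x1
  }
}

# Split-Rhat (Gelman et al.) for one parameter: draws is an iterations x chains
# matrix; each chain is split in half before computing the usual ratio.
split_rhat <- function(draws) {
  n <- nrow(draws)
  half <- floor(n / 2)
  if (half < 2L) return(NA_real_)
  parts <- cbind(draws[seq_len(half), , drop = FALSE],
                 draws[(n - half + 1):n, , drop = FALSE])
  m <- ncol(parts)
  means <- colMeans(parts)
  vars <- apply(parts, 2, stats::var)
  W <- mean(vars)
  B <- half * stats::var(means)
  var_plus <- (half - 1) / half * W + B / half
  if (W <= 0) return(1)
  sqrt(var_plus / W)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Parse ISO-8601 timestamps ("2019-01-01T13:00:00Z" or with a space) to
# POSIXct in UTC; returns NA where unparseable so callers can report rows.
parse_timestamp <- function(ts) {
  ts <- sub("Z$", "", ts)
  ts <- sub("T", " ", ts, fixed = TRUE)
  as.POSIXct(ts, tz = "UTC",
             tryFormats = c("%Y-%m-%d %H:%M:%S", "%Y-%m-%d %H:%M"),
             optional = TRUE)
}
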