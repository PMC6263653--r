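#' Hjorth mobility and complexity
#'
#' Mobility is `sqrt(var(dx) / var(x))` and complexity is
#' `mobility(dx) / mobility(x)`, with the derivative approximated by the
#' forward difference `dx[n] = x[n+1] - x[n]`. Mobility is an RMS-frequency
#' proxy, complexity a bandwidth proxy; both are invariant to amplitude
#' scaling. Sample variance (n - 1 denominator) is used throughout.
#'
#' @param x Numeric amplitude series of length >= 3.
#' @return Named numeric vector `c(mobility, complexity)`.
#' @export
hjorth_parameters <- function(x) {
  if (length(x) < 3) stop("`x` must have at least 3 samples")
  v <- stats::var(x)
  if (v == 0) stop("`x` has zero variance; Hjorth mobility is undefined")
  d <- diff(x)
  vd <- stats::var(d)
  mobility <- sqrt(vd / v)
  if (vd == 0)
    stop("first difference of `x` has zero variance; complexity is undefined (mobility would be 0)")
  vdd <- stats::var(diff(d))
  complexity <- sqrt(vdd / vd) / mobility
  c(mobility = mobility, complexity = complexity)
}

#' Shapiro-Wilk normality test on a (possibly long) series
#'
#' The W test is defined for 3 to 5000 observations; longer series are
#' reduced to an evenly-spaced deterministic subsample of `max_n` points
#' (no RNG involved) before testing.
#'
#' @param x Numeric series, length >= 3, non-constant.
#' @param max_n Maximum number of points passed to the test.
#' @return Named numeric vector `c(W, p)`.
#' @export
shapiro_wilk <- function(x, max_n = 5000) {
  if (length(x) < 3) stop("`x` must have at least 3 samples")
  if (stats::var(x) == 0) stop("`x` is constant; Shapiro-Wilk is undefined")
  if (length(x) > max_n)
    x <- x[round(seq(1, length(x), length.out = max_n))]
  sw <- stats::shapiro.test(x)
  c(W = unname(sw$statistic), p = unname(sw$p.value))
}

.time_feature_names <- c("min", "max", "mean", "variance", "std",
                         "coefficient_of_variation", "kurtosis", "skewness",
                         "q25", "q50", "q75", "shapiro_W", "shapiro_p",
                         "hjorth_mobility", "hjorth_complexity")

# The 15 time-domain descriptors of one channel. Kurtosis is excess
# (Fisher) and skewness adjusted Fisher-Pearson (e1071 type 2); quantiles
# use the linear-interpolation convention (type 7).
.channel_time_features <- function(x, channel) {
  if (stats::var(x) == 0)
    stop(sprintf("channel %s is constant; time features are undefined", channel))
  m <- mean(x)
  if (m == 0)
    stop(sprintf("channel %s has exactly zero mean; coefficient of variation is undefined", channel))
  v <- stats::var(x)
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  sw <- shapiro_wilk(x)
  hj <- hjorth_parameters(x)
  out <- c(min(x), max(x), m, v, sqrt(v), sqrt(v) / m,
           e1071::kurtosis(x, type = 2), e1071::skewness(x, type = 2),
           q[1], q[2], q[3], sw[["W"]], sw[["p"]],
           hj[["mobility"]], hj[["complexity"]])
  names(out) <- .time_feature_names
  out
}

#' Time-domain feature row for one recording
#'
#' Computes the 15 per-channel descriptors (min, max, mean, variance,
#' standard deviation, coefficient of variation, excess kurtosis, skewness,
#' quartiles, Shapiro-Wilk W and p, Hjorth mobility and complexity) for
#' every channel, channel-major, yielding `15 * n_channels` named features
#' (210 for the 14-channel montage). Names have the form
#' `{channel}_{feature}`.
#'
#' @param rec An [eeg_recording()] (typically the preprocessed task
#'   segment).
#' @return Named numeric vector of length `15 * n_channels`.
#' @export
time_feature_row <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  rows <- lapply(seq_along(rec$channel_labels), function(ch) {
    f <- .channel_time_features(rec$data[ch, ], rec$channel_labels[ch])
    names(f) <- paste(rec$channel_labels[ch], names(f), sep = "_")
    f
  })
  do.call(c, rows)
}
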