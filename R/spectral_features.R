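#' Canonical EEG frequency bands
#'
#' Theta 4-8, alpha 8-12, beta 12-30 and gamma 30-60 Hz. Band membership is
#' half-open, `[low, high)`, so shared edges are not double-counted (8 Hz
#' belongs to alpha, not theta). All spectral sums are additionally clipped
#' at the 43 Hz analysis limit imposed by the headset's low-pass filter, so
#' the effective gamma band is 30-43 Hz.
#'
#' @format Data frame with columns `band`, `low`, `high`.
#' @export
eeg_bands <- data.frame(band = c("theta", "alpha", "beta", "gamma"),
                        low = c(4, 8, 12, 30), high = c(8, 12, 30, 60),
                        stringsAsFactors = FALSE)

#' Upper frequency limit of the analysis (Hz)
#' @export
f_max_hz <- 43

.hann <- function(N) 0.5 * (1 - cos(2 * pi * (0:(N - 1)) / N))

#' Short-time Fourier transform
#'
#' Slices `x` into `window_length`-sample segments with the given fractional
#' overlap (hop = `window_length * (1 - overlap)`), tapers each with a
#' periodic Hann window (or none), and returns the complex FFT of every
#' segment. The number of segments is
#' `floor((length(x) - window_length) / hop) + 1`.
#'
#' @param x Numeric amplitude series.
#' @param window_length Segment length in samples (default 256, i.e. 2 s at
#'   128 Hz giving 0.5 Hz resolution).
#' @param overlap Fractional overlap in `[0, 1)` (default 0.5).
#' @param window `"hann"` or `"rect"` (no taper).
#' @return List of class `eeg_stft` with `fft` (complex
#'   `window_length x n_segments` matrix), `window_length`, `overlap`,
#'   `hop`, `window`.
#' @export
stft <- function(x, window_length = 256, overlap = 0.5,
                 window = c("hann", "rect")) {
  window <- match.arg(window)
  if (overlap < 0 || overlap >= 1) stop("`overlap` must be in [0, 1)")
  if (window_length > length(x))
    stop(sprintf("signal too short for STFT: need at least %d samples (window_length), got %d",
                 window_length, length(x)))
  hop <- round(window_length * (1 - overlap))
  if (hop < 1) stop("`overlap` too large: hop is below one sample")
  n_seg <- floor((length(x) - window_length) / hop) + 1
  w <- if (window == "hann") .hann(window_length) else rep(1, window_length)
  out <- matrix(complex(real = 0), window_length, n_seg)
  for (s in seq_len(n_seg)) {
    i0 <- (s - 1) * hop
    out[, s] <- stats::fft(w * x[(i0 + 1):(i0 + window_length)])
  }
  structure(list(fft = out, window_length = window_length, overlap = overlap,
                 hop = hop, window = window), class = "eeg_stft")
}

#' Periodogram power spectral density of one FFT segment
#'
#' `per(w) = |fft(w)|^2 / N`, folded to a one-sided spectrum on
#' `[0, fs/2]`: interior bins are doubled so that the one-sided sum equals
#' the two-sided sum, preserving Parseval's identity
#' `sum(per) = sum(x^2)` for an untapered segment.
#'
#' @param segment_fft Complex FFT vector of length `N`.
#' @param N Segment length in samples.
#' @param fs Sampling rate in Hz.
#' @return A `spectrum` object: list with `frequencies`, `power`,
#'   `normalization = "raw"`, `N`, `fs`.
#' @export
periodogram <- function(segment_fft, N = length(segment_fft), fs = 128) {
  if (N <= 0) stop("`N` must be positive")
  p2 <- Mod(segment_fft)^2 / N
  half <- floor(N / 2)
  p <- p2[1:(half + 1)]
  if (N %% 2 == 0) {
    if (half > 1) p[2:half] <- 2 * p[2:half]
  } else {
    p[2:(half + 1)] <- 2 * p[2:(half + 1)]
  }
  structure(list(frequencies = (0:half) * fs / N, power = p,
                 normalization = "raw", N = N, fs = fs),
            class = "eeg_spectrum")
}

#' Normalize a periodogram to unit total power
#'
#' Divides the power at every bin by the total, so bins express each
#' frequency's relative contribution; shape (bin ratios) is preserved and
#' the output sums to one.
#'
#' @param p An `eeg_spectrum` from [periodogram()] or [avg_periodogram()].
#' @return The spectrum with `normalization = "relative"`.
#' @export
normalize_periodogram <- function(p) {
  stopifnot(inherits(p, "eeg_spectrum"))
  tot <- sum(p$power)
  if (tot <= 0) stop("cannot normalize an all-zero spectrum")
  p$power <- p$power / tot
  p$normalization <- "relative"
  p
}

#' Segment-averaged periodogram of a signal
#'
#' Averages the one-sided periodograms of Hann-tapered, 50%-overlapping
#' segments (the averaged-modified-periodogram PSD estimate, up to the
#' constant window-power factor, which cancels in every relative and ratio
#' quantity used downstream).
#'
#' @inheritParams stft
#' @param fs Sampling rate in Hz.
#' @return An `eeg_spectrum` with `normalization = "raw"` and an
#'   `n_segments` element.
#' @export
avg_periodogram <- function(x, fs = 128, window_length = 256, overlap = 0.5,
                            window = "hann") {
  st <- stft(x, window_length, overlap, window)
  n_seg <- ncol(st$fft)
  acc <- NULL
  for (s in seq_len(n_seg)) {
    p <- periodogram(st$fft[, s], window_length, fs)
    acc <- if (is.null(acc)) p$power else acc + p$power
  }
  p$power <- acc / n_seg
  p$n_segments <- n_seg
  p
}

#' Relative band powers of a normalized spectrum
#'
#' Sums the normalized periodogram bins whose frequency lies in
#' `[low, min(high, f_max))` for each band.
#'
#' @param p An `eeg_spectrum` with `normalization = "relative"` (see
#'   [normalize_periodogram()]).
#' @param bands Band definition data frame (default [eeg_bands]).
#' @param f_max Upper analysis limit in Hz (default 43).
#' @return Named numeric vector of per-band relative powers.
#' @export
band_powers <- function(p, bands = eeg_bands, f_max = f_max_hz) {
  stopifnot(inherits(p, "eeg_spectrum"))
  if (identical(p$normalization, "raw"))
    stop("`p` must be a relative (normalized) spectrum; see normalize_periodogram()")
  if (any(bands$low < 0) || any(bands$low >= p$fs / 2))
    stop("band edges outside [0, fs/2]")
  out <- vapply(seq_len(nrow(bands)), function(i) {
    hi <- min(bands$high[i], f_max)
    sum(p$power[p$frequencies >= bands$low[i] & p$frequencies < hi])
  }, numeric(1))
  names(out) <- bands$band
  out
}

# raw (unnormalized) band power sums, used for dB baseline normalization
.raw_band_powers <- function(p, bands = eeg_bands, f_max = f_max_hz) {
  out <- vapply(seq_len(nrow(bands)), function(i) {
    hi <- min(bands$high[i], f_max)
    sum(p$power[p$frequencies >= bands$low[i] & p$frequencies < hi])
  }, numeric(1))
  names(out) <- bands$band
  out
}

#' Decibel baseline normalization
#'
#' `10 * log10(activity / baseline)`: the change of task-period power
#' relative to resting-baseline power, in dB. This removes the 1/f power
#' scaling and subject-specific amplitude factors (scalp/hair/skull
#' differences) that make raw power incomparable across frequencies and
#' subjects.
#'
#' @param activity_power Non-negative task-period power (scalar or vector).
#' @param baseline_power Strictly positive baseline power of matching
#'   length (or length 1).
#' @return Power change in dB.
#' @export
db_normalize <- function(activity_power, baseline_power) {
  if (any(baseline_power <= 0)) stop("`baseline_power` must be strictly positive")
  if (any(activity_power < 0)) stop("`activity_power` must be non-negative")
  10 * log10(activity_power / baseline_power)
}

#' Spectral feature row for one recording
#'
#' For each channel, computes the segment-averaged Hann periodogram of the
#' task segment and emits 5 features: the four band powers (theta, alpha,
#' beta, gamma) and the total average power (mean raw periodogram value
#' across bins and segments) - 70 features for the 14-channel montage.
#' With `normalize_db = TRUE` (the default) the band features are
#' dB-normalized against the baseline segment's band powers (Eq.-style
#' `10 log10(task/baseline)`); otherwise they are relative powers of the
#' task spectrum. Names are `{channel}_{band}_db` / `_rel` and
#' `{channel}_total_power`.
#'
#' @param task Task-segment [eeg_recording()].
#' @param baseline Baseline-segment [eeg_recording()] (required when
#'   `normalize_db = TRUE`).
#' @param window_length,overlap STFT parameters (defaults 256 samples, 0.5).
#' @param bands Band definitions (default [eeg_bands]).
#' @param f_max Upper analysis limit (default 43 Hz).
#' @param normalize_db Use decibel baseline normalization for the band
#'   features (default `TRUE`).
#' @return Named numeric vector of `5 * n_channels` features.
#' @export
spectral_feature_row <- function(task, baseline = NULL, window_length = 256,
                                 overlap = 0.5, bands = eeg_bands,
                                 f_max = f_max_hz, normalize_db = TRUE) {
  stopifnot(inherits(task, "eeg_recording"))
  if (normalize_db) {
    if (is.null(baseline)) stop("`baseline` is required when normalize_db = TRUE")
    stopifnot(inherits(baseline, "eeg_recording"))
    if (n_samples(baseline) < window_length)
      stop(sprintf("baseline shorter than one STFT window: need at least %d samples (%.2f s at %g Hz)",
                   window_length, window_length / baseline$fs, baseline$fs))
  }
  rows <- lapply(seq_along(task$channel_labels), function(ch) {
    pt <- avg_periodogram(task$data[ch, ], task$fs, window_length, overlap)
    total_power <- mean(pt$power)
    if (normalize_db) {
      pb <- avg_periodogram(baseline$data[ch, ], baseline$fs, window_length,
                            overlap)
      bp <- db_normalize(.raw_band_powers(pt, bands, f_max),
                         .raw_band_powers(pb, bands, f_max))
      nm <- paste0(bands$band, "_db")
    } else {
      bp <- band_powers(normalize_periodogram(pt), bands, f_max)
      nm <- paste0(bands$band, "_rel")
    }
    f <- c(bp, total_power)
    names(f) <- paste(task$channel_labels[ch], c(nm, "total_power"), sep = "_")
    f
  })
  do.call(c, rows)
}
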