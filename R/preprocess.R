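#' Remove the DC offset with a first-order high-pass filter
#'
#' One-pole leaky DC blocker `y[n] = x[n] - x[n-1] + a * y[n-1]`, with `a`
#' chosen so the -3 dB point sits at `cutoff_hz` (0.16 Hz by default, the
#' headset's stated cutoff). The filter's leaky-mean state is initialized
#' to the mean of the first second of signal, so an exactly constant
#' channel maps to exactly zero and the start-up transient stays within
#' the amplitude of the slow signal content. Content above 1 Hz is
#' attenuated by less than 0.1 dB; passband gain deviates from unity by
#' under 0.5%.
#'
#' @param rec An [eeg_recording()].
#' @param cutoff_hz High-pass -3 dB frequency in Hz.
#' @return The filtered [eeg_recording()].
#' @export
remove_dc <- function(rec, cutoff_hz = 0.16) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (n_samples(rec) < 2) stop("need at least 2 samples to high-pass filter")
  a <- exp(-2 * pi * cutoff_hz / rec$fs)
  out <- rec
  n0 <- min(round(rec$fs), n_samples(rec))
  for (ch in seq_len(nrow(rec$data))) {
    x <- rec$data[ch, ]
    dx <- c(x[1] - mean(x[1:n0]), diff(x))
    out$data[ch, ] <- as.numeric(stats::filter(dx, a, method = "recursive"))
  }
  out
}

#' Reject amplitude outliers
#'
#' Flags every sample whose absolute amplitude exceeds `k` times the
#' channel's mean absolute amplitude, and drops the union of flagged time
#' points across channels (whole cross-channel time points, keeping the
#' matrix rectangular). Retained amplitudes are never altered. The baseline
#' span is re-indexed onto the retained samples.
#'
#' @param rec An [eeg_recording()]; intended to be applied after
#'   [remove_dc()] (on a signal with a large offset the mean-amplitude
#'   threshold is dominated by the offset).
#' @param k Threshold multiplier (default 3).
#' @return A list with `recording` (the cleaned [eeg_recording()]) and
#'   `report` (variant, scalar `fraction_removed`, per-channel flagged
#'   fractions, per-channel thresholds).
#' @export
remove_outliers <- function(rec, k = 3) {
  stopifnot(inherits(rec, "eeg_recording"))
  thr <- k * rowMeans(abs(rec$data))
  if (any(thr == 0)) stop("channel with zero mean absolute amplitude")
  flagged <- abs(rec$data) > thr
  drop_t <- which(colSums(flagged) > 0)
  if (length(drop_t) == n_samples(rec))
    stop("all time points flagged as outliers; input is degenerate")
  keep <- setdiff(seq_len(n_samples(rec)), drop_t)
  out <- rec
  out$data <- rec$data[, keep, drop = FALSE]
  s <- rec$baseline_span
  out$baseline_span <- c(sum(keep <= s[1]), sum(keep <= s[2]))
  report <- list(variant = "NoOutliers",
                 fraction_removed = length(drop_t) / n_samples(rec),
                 per_channel_flagged = rowMeans(flagged),
                 threshold = thr, k = k)
  list(recording = out, report = report)
}

#' Split a recording into its baseline and task segments
#'
#' @param rec An [eeg_recording()] with a nonempty baseline span.
#' @return A list with `baseline` and `task` recordings. Concatenating the
#'   two reconstructs the input; the task segment carries an empty baseline
#'   span. An empty task segment (baseline covering the whole recording) is
#'   an error.
#' @export
split_baseline <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!has_baseline(rec)) stop("`rec` has an empty baseline_span")
  bi <- baseline_indices(rec)
  ti <- setdiff(seq_len(n_samples(rec)), bi)
  if (length(ti) == 0) stop("baseline span covers the whole recording; task segment is empty")
  baseline <- eeg_recording(rec$data[, bi, drop = FALSE], rec$fs,
                            rec$channel_labels,
                            baseline_span = c(0L, length(bi)),
                            subject_id = rec$subject_id)
  task <- eeg_recording(rec$data[, ti, drop = FALSE], rec$fs,
                        rec$channel_labels, baseline_span = c(0L, 0L),
                        subject_id = rec$subject_id)
  list(baseline = baseline, task = task)
}

#' Apply one of the three preprocessing variants
#'
#' `"raw"` leaves the recording untouched; `"nodc"` applies [remove_dc()]
#' and discards the first `settle_s` seconds (filter settling);
#' `"nooutliers"` additionally applies [remove_outliers()] to the
#' DC-removed signal. Outlier rejection is always computed on DC-removed
#' data, matching the raw -> NoDC -> NoOutliers ordering of the analysis.
#'
#' @param rec An [eeg_recording()].
#' @param variant `"raw"`, `"nodc"` or `"nooutliers"`.
#' @param k Outlier threshold multiplier.
#' @param settle_s Seconds discarded from the start after filtering.
#' @return A list with `recording` and `report` (variant and
#'   `fraction_removed`).
#' @export
preprocess_variant <- function(rec, variant = c("nodc", "raw", "nooutliers"),
                               k = 3, settle_s = 1) {
  variant <- match.arg(variant)
  if (variant == "raw")
    return(list(recording = rec,
                report = list(variant = "raw", fraction_removed = 0)))
  out <- remove_dc(rec)
  n_settle <- min(round(settle_s * rec$fs), n_samples(out) - 1L)
  if (n_settle > 0) {
    out$data <- out$data[, -(seq_len(n_settle)), drop = FALSE]
    s <- rec$baseline_span
    out$baseline_span <- c(max(s[1] - n_settle, 0L), max(s[2] - n_settle, 0L))
  }
  if (variant == "nodc")
    return(list(recording = out,
                report = list(variant = "NoDC", fraction_removed = 0)))
  res <- remove_outliers(out, k = k)
  res
}
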