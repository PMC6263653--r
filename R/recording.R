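#' Montage channel labels of the 14-channel wireless headset
#'
#' Electrode labels, in fixed order, of the 10-20-system montage used
#' throughout the package (frontal, fronto-central, temporal, parietal and
#' occipital sites). Feature names are derived channel-major from this order.
#'
#' @format Character vector of length 14.
#' @export
emotiv_channels <- c("AF3", "AF4", "F3", "F4", "FC5", "FC6", "F7", "F8",
                     "T7", "T8", "P7", "P8", "O1", "O2")

#' Construct a multichannel EEG recording
#'
#' Container for a channels-by-samples amplitude matrix (microvolts) with its
#' sampling rate, channel labels, an optional resting-baseline span and a
#' subject identifier. The baseline span is half-open, `[start, end)`, in
#' 0-based sample indices (matching the on-disk sample-index column).
#'
#' @param data Numeric matrix, channels in rows, samples in columns. No
#'   missing values are allowed.
#' @param fs Sampling rate in Hz.
#' @param channel_labels Character vector of unique channel names, one per
#'   row of `data`. Defaults to `rownames(data)`.
#' @param baseline_span Integer length-2 vector `c(start, end)`, half-open,
#'   0-based. `c(0, 0)` means "no baseline".
#' @param subject_id Optional subject identifier.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, channel_labels = rownames(data),
                          baseline_span = c(0L, 0L), subject_id = NA_character_) {
  if (!is.matrix(data) || !is.numeric(data))
    stop("`data` must be a numeric channels x samples matrix")
  if (anyNA(data)) stop("`data` must not contain missing values")
  if (is.null(channel_labels))
    channel_labels <- paste0("CH", seq_len(nrow(data)))
  if (length(channel_labels) != nrow(data))
    stop("`channel_labels` must have one entry per channel (row)")
  if (anyDuplicated(channel_labels))
    stop("`channel_labels` must be unique")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a single positive sampling rate in Hz")
  baseline_span <- as.integer(round(baseline_span))
  if (length(baseline_span) != 2L || baseline_span[1] < 0L ||
      baseline_span[2] < baseline_span[1] || baseline_span[2] > ncol(data))
    stop("`baseline_span` must be half-open [start, end) within [0, n_samples]")
  rownames(data) <- channel_labels
  structure(
    list(data = data, fs = fs, channel_labels = channel_labels,
         baseline_span = baseline_span, subject_id = subject_id),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  bl <- diff(x$baseline_span) / x$fs
  cat(sprintf("<eeg_recording> %s: %d channels x %d samples @ %g Hz (%.1f s), baseline %.1f s\n",
              x$subject_id, nrow(x$data), ncol(x$data), x$fs,
              ncol(x$data) / x$fs, bl))
  invisible(x)
}

n_samples <- function(rec) ncol(rec$data)

# 1-based column indices of the baseline span
baseline_indices <- function(rec) {
  s <- rec$baseline_span
  if (s[2] <= s[1]) integer(0) else (s[1] + 1L):s[2]
}

has_baseline <- function(rec) rec$baseline_span[2] > rec$baseline_span[1]
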