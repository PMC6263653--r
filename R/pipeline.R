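#' Pipeline configuration
#'
#' Collects every stage's settings: acquisition constants, preprocessing
#' variant, band definitions, STFT parameters, selector settings and the
#' cross-validation protocol. Defaults reproduce the study settings
#' (128 Hz, 14-channel montage, 36 s baseline, 256-sample Hann windows at
#' 50% overlap, bands clipped at 43 Hz, l1 selection, k = 10).
#' Serializes losslessly to YAML via [write_config()] / [read_config()].
#'
#' @param fs Sampling rate (Hz).
#' @param channels Channel labels.
#' @param baseline_s Baseline length (s).
#' @param variant Preprocessing variant: `"raw"`, `"nodc"`, `"nooutliers"`.
#' @param k_outlier Outlier threshold multiplier.
#' @param window_length,overlap STFT parameters.
#' @param bands Band definitions (data frame `band`, `low`, `high`).
#' @param f_max Upper analysis frequency (Hz).
#' @param normalize_db Use dB baseline normalization for band features.
#' @param penalty,lambda Feature-selector settings.
#' @param k Cross-validation folds.
#' @param seed Master seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(fs = 128, channels = emotiv_channels,
                            baseline_s = 36, variant = "nodc", k_outlier = 3,
                            window_length = 256, overlap = 0.5,
                            bands = eeg_bands, f_max = f_max_hz,
                            normalize_db = TRUE, penalty = "l1",
                            lambda = 0.01, k = 10, seed = 1) {
  structure(list(fs = fs, channels = channels, baseline_s = baseline_s,
                 variant = variant, k_outlier = k_outlier,
                 window_length = window_length, overlap = overlap,
                 bands = bands, f_max = f_max, normalize_db = normalize_db,
                 penalty = penalty, lambda = lambda, k = as.integer(k),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path File path for the YAML serialization.
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  x$bands <- as.list(x$bands)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$bands <- data.frame(band = x$bands$band, low = x$bands$low,
                        high = x$bands$high, stringsAsFactors = FALSE)
  do.call(pipeline_config, x)
}

#' Extract the feature table for a set of recordings
#'
#' Applies the configured preprocessing variant to each recording, splits
#' baseline from task, and assembles one row per subject of time-domain
#' (15 per channel), spectral (5 per channel) or combined features - 210,
#' 70 or 280 columns for the 14-channel montage, plus `subject_id`.
#'
#' @param recordings List of [eeg_recording()]s.
#' @param features `"combined"`, `"time"` or `"freq"`.
#' @param config A [pipeline_config()].
#' @return A data frame: `subject_id` plus named feature columns. The
#'   per-subject preprocessing reports are attached as attribute
#'   `"reports"`.
#' @export
feature_table <- function(recordings, features = c("combined", "time", "freq"),
                          config = pipeline_config()) {
  features <- match.arg(features)
  rows <- vector("list", length(recordings))
  reports <- vector("list", length(recordings))
  for (i in seq_along(recordings)) {
    pp <- preprocess_variant(recordings[[i]], config$variant,
                             k = config$k_outlier)
    reports[[i]] <- pp$report
    seg <- split_baseline(pp$recording)
    row <- numeric(0)
    if (features %in% c("combined", "time"))
      row <- c(row, time_feature_row(seg$task))
    if (features %in% c("combined", "freq"))
      row <- c(row, spectral_feature_row(seg$task, seg$baseline,
                                         config$window_length,
                                         config$overlap, config$bands,
                                         config$f_max, config$normalize_db))
    rows[[i]] <- row
  }
  ids <- vapply(recordings, function(r) r$subject_id, character(1))
  out <- cbind(data.frame(subject_id = ids, stringsAsFactors = FALSE),
               as.data.frame(do.call(rbind, rows), check.names = FALSE))
  attr(out, "reports") <- reports
  out
}

# ---- delimited I/O -------------------------------------------------------

.fmt17 <- function(x) sprintf("%.17g", x)

#' Write / read a recording in the delimited dialect
#'
#' Comma-delimited, UTF-8, '.' decimal: a header row of channel labels
#' preceded by a `sample_index` column (0-based), one row per sample,
#' amplitudes printed with 17 significant digits so the round trip is
#' bit-exact. Metadata (sampling rate, baseline span, subject id) is not
#' stored in the file; supply it to `read_recording()` (the pipeline's
#' manifest records it).
#'
#' @param rec An [eeg_recording()].
#' @param path Output path. `.edf` paths are rejected with an informative
#'   error: recordings are exchanged in the delimited dialect.
#' @export
write_recording <- function(rec, path) {
  if (grepl("\\.edf$", path, ignore.case = TRUE))
    stop("EDF output is not supported; write the delimited dialect (.csv)")
  df <- data.frame(sample_index = 0:(n_samples(rec) - 1))
  for (ch in seq_along(rec$channel_labels))
    df[[rec$channel_labels[ch]]] <- .fmt17(rec$data[ch, ])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_recording
#' @param fs Sampling rate of the stored recording (Hz); must match the
#'   rate expected by the caller - there is no silent resampling.
#' @param baseline_span Half-open 0-based `c(start, end)` baseline span.
#' @param subject_id Subject identifier.
#' @param channel_labels Expected channel labels; a mismatch with the file
#'   header is an error naming the offending labels.
#' @export
read_recording <- function(path, fs = 128, baseline_span = c(0L, 0L),
                           subject_id = NA_character_,
                           channel_labels = NULL) {
  if (grepl("\\.edf$", path, ignore.case = TRUE))
    stop("EDF input is not supported; supply the delimited dialect (.csv)")
  df <- utils::read.csv(path, check.names = FALSE)
  if (names(df)[1] != "sample_index")
    stop("first column must be `sample_index`")
  found <- names(df)[-1]
  if (!is.null(channel_labels) && !identical(found, channel_labels)) {
    bad <- c(setdiff(found, channel_labels), setdiff(channel_labels, found))
    stop("channel labels do not match the expected montage: ",
         paste(unique(bad), collapse = ", "))
  }
  data <- t(as.matrix(df[-1]))
  eeg_recording(data, fs, channel_labels = found,
                baseline_span = baseline_span, subject_id = subject_id)
}

#' Write / read a feature or score table
#'
#' Comma-delimited with a header row and 17-significant-digit numerics
#' (lossless round trip). Score tables use columns
#' `subject_id`, `FA`, `WM`.
#'
#' @param table Data frame.
#' @param path File path.
#' @export
write_features <- function(table, path) {
  fmt <- table
  for (j in seq_along(fmt))
    if (is.numeric(fmt[[j]])) fmt[[j]] <- .fmt17(fmt[[j]])
  utils::write.csv(fmt, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' @rdname write_features
#' @param scores Data frame with `subject_id`, `fa_score`, `wm_score`.
#' @export
write_scores <- function(scores, path) {
  df <- data.frame(subject_id = scores$subject_id,
                   FA = .fmt17(scores$fa_score),
                   WM = .fmt17(scores$wm_score))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_scores <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "FA", "WM")
  if (!all(need %in% names(df)))
    stop("score table must have columns subject_id, FA, WM; missing: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  data.frame(subject_id = df$subject_id, fa_score = df$FA,
             wm_score = df$WM,
             fa_label = as.character(encode_score(df$FA)),
             wm_label = as.character(encode_score(df$WM)),
             stringsAsFactors = FALSE)
}

# ---- end-to-end orchestration -------------------------------------------

#' Run the full pipeline from recordings to the comparison table
#'
#' Either simulates a cohort (`simulate = cohort_config(...)`) or loads
#' recordings and scores from `input_dir` (one `<subject_id>.csv` per
#' recording in the delimited dialect plus a `scores.csv`). Preprocesses
#' with the configured variant, extracts the requested feature set, runs
#' the classifier comparison per skill under stratified k-fold CV, and
#' writes the feature table, score table, comparison table and a JSON
#' manifest (config hash, seeds, per-subject removed-sample fractions)
#' into `out_dir`.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param simulate A [cohort_config()] to simulate instead of reading.
#' @param input_dir Directory of on-disk recordings (used when `simulate`
#'   is `NULL`).
#' @param features `"combined"`, `"time"` or `"freq"`.
#' @param zoo Classifier specs (default the full [classifier_zoo()]).
#' @param skills Which skill targets to classify.
#' @return Invisibly, a list with `features`, `scores`, `reports` (per
#'   skill), `table` and `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir,
                         simulate = NULL, input_dir = NULL,
                         features = "combined", zoo = classifier_zoo(),
                         skills = c("fa", "wm")) {
  if (is.null(simulate) && is.null(input_dir))
    stop("either `simulate` (a cohort_config) or `input_dir` is required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(simulate)) {
    cohort <- generate_cohort(simulate)
  } else {
    scores <- read_scores(file.path(input_dir, "scores.csv"))
    paths <- file.path(input_dir, paste0(scores$subject_id, ".csv"))
    missing <- scores$subject_id[!file.exists(paths)]
    if (length(missing))
      stop("missing recordings for subjects: ", paste(missing, collapse = ", "))
    recs <- lapply(seq_along(paths), function(i)
      read_recording(paths[i], fs = config$fs,
                     baseline_span = c(0L, round(config$baseline_s * config$fs)),
                     subject_id = scores$subject_id[i],
                     channel_labels = config$channels))
    cohort <- list(recordings = recs, scores = scores)
  }
  feats <- feature_table(cohort$recordings, features, config)
  X <- as.matrix(feats[, -1, drop = FALSE])
  reports <- list()
  for (sk in skills) {
    y <- factor(cohort$scores[[paste0(sk, "_label")]], levels = skill_levels)
    reports[[sk]] <- run_comparison(X, y, zoo = zoo, k = config$k,
                                    seed = config$seed,
                                    penalty = config$penalty,
                                    lambda = config$lambda)
  }
  tab <- report_table(reports)
  write_features(feats, file.path(out_dir, "features.csv"))
  write_scores(cohort$scores, file.path(out_dir, "scores.csv"))
  write_report_table(tab, file.path(out_dir, "comparison.csv"))
  cfg_path <- file.path(out_dir, "config.yaml")
  write_config(config, cfg_path)
  pp <- attr(feats, "reports")
  manifest <- list(
    config_hash = unname(tools::md5sum(cfg_path)),
    seed = config$seed,
    n_subjects = nrow(feats),
    n_features = ncol(feats) - 1L,
    feature_set = features,
    variant = config$variant,
    simulated = !is.null(simulate),
    cohort = if (!is.null(simulate)) unclass(simulate),
    fraction_removed = vapply(pp, function(r) r$fraction_removed, numeric(1))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(features = feats, scores = cohort$scores,
                 reports = reports, table = tab, manifest = manifest))
}
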