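#' Configuration of a synthetic EEG cohort
#'
#' Bundles the acquisition constants (128 Hz, 14 channels, 36 s baseline)
#' with the simulator's knobs: task duration, planted class-effect size,
#' spike-artifact rate and DC offset.
#'
#' @param n_subjects Number of subjects (>= 3).
#' @param duration_s Seconds of task recording per subject.
#' @param baseline_s Seconds of resting baseline preceding the task
#'   (default 36: 15 s eyes open + 15 s eyes closed + 6 s get-ready).
#' @param fs Sampling rate in Hz (default 128). Must exceed twice the 43 Hz
#'   upper analysis limit.
#' @param n_channels Number of channels (default 14, the montage length).
#' @param effect_size Dimensionless multiplier on the planted per-class
#'   band-power shift; 0 makes recordings label-independent, 1 separates
#'   adjacent classes by about one within-class standard deviation per
#'   channel in the signature bands.
#' @param artifact_rate Spike artifacts per minute per channel. The default
#'   (0.8) makes the 3x-mean-amplitude outlier rule, applied across
#'   channels, remove about 0.3% of time points.
#' @param dc_offset Constant acquisition offset in microvolts added to every
#'   sample (default 50).
#' @param seed Master RNG seed for the cohort.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 90, duration_s = 120, baseline_s = 36,
                          fs = 128, n_channels = 14, effect_size = 1,
                          artifact_rate = 0.8, dc_offset = 50, seed = 1) {
  if (n_subjects < 3) stop("`n_subjects` must be at least 3")
  if (baseline_s < 30) stop("`baseline_s` must be at least 30 s")
  if (fs <= 2 * 43) stop("`fs` must exceed twice the 43 Hz analysis limit")
  if (n_channels < 1) stop("`n_channels` must be positive")
  if (effect_size < 0) stop("`effect_size` must be non-negative")
  if (artifact_rate < 0) stop("`artifact_rate` must be non-negative")
  structure(list(n_subjects = as.integer(n_subjects), duration_s = duration_s,
                 baseline_s = baseline_s, fs = fs,
                 n_channels = as.integer(n_channels),
                 effect_size = effect_size, artifact_rate = artifact_rate,
                 dc_offset = dc_offset, seed = as.integer(seed)),
            class = "cohort_config")
}

skill_levels <- c("low", "moderate", "high")

# Baseline oscillation RMS per band (uV) and background RMS (uV); plausible
# resting-EEG magnitudes for a dry-electrode consumer headset.
.band_rms <- c(theta = 8, alpha = 10, beta = 6, gamma = 3)
.background_rms <- 15
.subject_scale_sd <- 0.3   # log-scale between-subject amplitude variation
.band_jitter_sd <- 0.15    # log-scale within-subject per-channel band jitter

#' Per-class band-power signature
#'
#' A 3 x 4 matrix of multiplicative band-amplitude factors (classes
#' low/moderate/high in rows, bands theta/alpha/beta/gamma in columns)
#' applied to the task-period oscillations. Focused attention modulates the
#' theta and alpha bands; working memory modulates beta and gamma. Adjacent
#' classes differ by a factor `1 + effect_size * step` in the signature
#' bands, which at the default within-class jitter corresponds to roughly
#' one within-class standard deviation per channel at `effect_size = 1`.
#'
#' @param skill `"fa"` (theta/alpha signature) or `"wm"` (beta/gamma).
#' @param effect_size Planted effect multiplier (see [cohort_config()]).
#' @param step Base fractional amplitude step between adjacent classes.
#' @return A numeric matrix of class `class_signature`.
#' @export
class_signature <- function(skill = c("fa", "wm"), effect_size = 1,
                            step = 0.25) {
  skill <- match.arg(skill)
  bands <- names(.band_rms)
  m <- matrix(1, 3, 4, dimnames = list(skill_levels, bands))
  sig_bands <- if (skill == "fa") c("theta", "alpha") else c("beta", "gamma")
  for (b in sig_bands) m[, b] <- (1 + effect_size * step)^(0:2)
  structure(m, class = c("class_signature", "matrix", "array"), skill = skill)
}

default_signatures <- function(effect_size = 1) {
  list(fa = class_signature("fa", effect_size),
       wm = class_signature("wm", effect_size))
}

#' Generate skewed cognitive scores on the 0-800 scale
#'
#' Draws from a scaled Beta family: `800 * Beta(2, 6)` for a
#' positively-skewed distribution (as observed for focused attention) and
#' `800 * Beta(6, 2)` for a negatively-skewed one (working memory). Support
#' is `[0, 800]` by construction, with the skew sign forced by the shape
#' parameters.
#'
#' @param n Number of scores.
#' @param skew `"positive"` or `"negative"`.
#' @param seed RNG seed.
#' @return Numeric vector of `n` scores in `[0, 800]`.
#' @export
generate_scores <- function(n, skew = c("positive", "negative"), seed = 1) {
  if (n < 1) stop("`n` must be at least 1")
  if (!is.character(skew) || !all(skew %in% c("positive", "negative")))
    stop("`skew` must be \"positive\" or \"negative\"")
  skew <- match.arg(skew)
  set.seed(as.integer(seed))
  if (skew == "positive") 800 * stats::rbeta(n, 2, 6) else 800 * stats::rbeta(n, 6, 2)
}

# Synthesize a unit-RMS random signal of length L whose amplitude spectrum
# follows `shape(f)` (evaluated on the positive FFT frequencies), by drawing
# complex Gaussian Fourier coefficients and inverse-transforming.
.synth_shaped <- function(L, fs, shape) {
  hf <- floor(L / 2)
  f <- (1:hf) * fs / L
  amp <- shape(f)
  co <- amp * complex(real = stats::rnorm(hf), imaginary = stats::rnorm(hf))
  spec <- complex(real = numeric(L))
  spec[2:(hf + 1)] <- co
  # conjugate-symmetric negative frequencies; Nyquist bin made real for even L
  if (L %% 2 == 0) spec[hf + 1] <- complex(real = Re(co[hf]) * sqrt(2))
  idx <- if (L %% 2 == 0) 2:hf else 2:(hf + 1)
  spec[L + 2 - idx] <- Conj(spec[idx])
  x <- Re(stats::fft(spec, inverse = TRUE)) / L
  r <- rms(x)
  if (r == 0) x else x / r
}

# 1/f-shaped background limited to 1-43 Hz: above by the headset's effective
# low-pass, below so that the DC-blocking high-pass leaves the signal (and
# hence the 3x-mean outlier threshold) essentially unchanged.
.shape_background <- function(f) ifelse(f >= 1 & f < 43, 1 / sqrt(f), 0)

.shape_band <- function(low, high) {
  force(low); force(high)
  function(f) as.numeric(f >= low & f < min(high, 43))
}

.band_edges <- list(theta = c(4, 8), alpha = c(8, 12), beta = c(12, 30),
                    gamma = c(30, 43))

# Core single-recording synthesis. `mult` is a named length-4 vector of
# task-period band-amplitude multipliers (baseline always uses 1).
.generate_eeg <- function(cfg, mult, seed, subject_id = NA_character_) {
  fs <- cfg$fs
  n_base <- round(cfg$baseline_s * fs)
  n_task <- round(cfg$duration_s * fs)
  if (n_task < 256)
    stop(sprintf("task duration too short for one STFT window: need at least %.2f s (256 samples at %g Hz)",
                 256 / fs, fs))
  n_tot <- n_base + n_task
  set.seed(as.integer(seed))
  subj_scale <- exp(stats::rnorm(1, 0, .subject_scale_sd))
  data <- matrix(0, cfg$n_channels, n_tot)
  for (ch in seq_len(cfg$n_channels)) {
    seg <- list(numeric(n_base), numeric(n_task))
    lens <- c(n_base, n_task)
    for (s in 1:2) {
      L <- lens[s]
      x <- .background_rms * .synth_shaped(L, fs, .shape_background)
      jit <- exp(stats::rnorm(4, 0, .band_jitter_sd))
      names(jit) <- names(.band_rms)
      for (b in names(.band_rms)) {
        m <- if (s == 2) mult[[b]] else 1
        amp <- .band_rms[[b]] * jit[[b]] * m
        x <- x + amp * .synth_shaped(L, fs, do.call(.shape_band, as.list(.band_edges[[b]])))
      }
      seg[[s]] <- subj_scale * x
    }
    x <- c(seg[[1]], seg[[2]])
    # bound the artifact-free signal strictly below the 3x mean-|x| outlier
    # threshold so only planted spikes can trip the rule
    lim <- 2.75 * mean(abs(x))
    x <- pmin(pmax(x, -lim), lim)
    # Poisson-placed spike artifacts, width 1-3 samples, amplitude 4-8x the
    # channel RMS, replacing the underlying samples
    n_spikes <- stats::rpois(1, cfg$artifact_rate * n_tot / fs / 60)
    if (n_spikes > 0) {
      pos <- sample.int(n_tot, n_spikes)
      wid <- sample(1:3, n_spikes, replace = TRUE)
      amp <- stats::runif(n_spikes, 4, 8) * rms(x) *
        sample(c(-1, 1), n_spikes, replace = TRUE)
      for (i in seq_len(n_spikes)) {
        j <- pos[i]:min(pos[i] + wid[i] - 1L, n_tot)
        x[j] <- amp[i]
      }
    }
    data[ch, ] <- x + cfg$dc_offset
  }
  eeg_recording(data, fs,
                channel_labels = emotiv_channels[seq_len(cfg$n_channels)],
                baseline_span = c(0L, n_base), subject_id = subject_id)
}

#' Generate one synthetic EEG recording for a given class label
#'
#' Synthesizes a baseline-plus-task recording: 1/f-shaped background
#' (band-limited below 43 Hz), band-limited theta/alpha/beta/gamma
#' oscillations whose task-period amplitudes are modulated by the class row
#' of `signature`, a constant DC offset, and Poisson-placed spike artifacts
#' that exceed the 3x mean-absolute-amplitude outlier threshold. With
#' `effect_size = 0` in the signature the output is independent of `label`.
#'
#' @param label Class label: `"low"`, `"moderate"` or `"high"`.
#' @param cfg A [cohort_config()].
#' @param signature A [class_signature()].
#' @param seed RNG seed (defaults to `cfg$seed`).
#' @param subject_id Optional identifier stored in the recording.
#' @return An [eeg_recording()].
#' @export
generate_recording <- function(label, cfg, signature = class_signature("fa", cfg$effect_size),
                               seed = cfg$seed, subject_id = NA_character_) {
  if (!label %in% skill_levels)
    stop("`label` must be one of \"low\", \"moderate\", \"high\"")
  .generate_eeg(cfg, mult = signature[label, ], seed = seed,
                subject_id = subject_id)
}

#' Generate a full synthetic cohort of recordings and cognitive scores
#'
#' Subjects are assigned balanced low/moderate/high labels per skill
#' (independently for focused attention and working memory), scores are
#' drawn uniformly within each label's score range, and each recording is
#' synthesized with the product of the two skills' band signatures so that
#' both labels are recoverable from the planted band powers. Fully
#' reproducible from `cfg$seed`.
#'
#' @param cfg A [cohort_config()].
#' @param signatures Named list with elements `fa` and `wm`, each a
#'   [class_signature()]. Defaults to the standard signatures at
#'   `cfg$effect_size`.
#' @return A list with `recordings` (list of [eeg_recording()]) and
#'   `scores` (data frame: subject_id, fa_score, wm_score, fa_label,
#'   wm_label).
#' @export
generate_cohort <- function(cfg, signatures = default_signatures(cfg$effect_size)) {
  stopifnot(inherits(cfg, "cohort_config"),
            all(c("fa", "wm") %in% names(signatures)))
  n <- cfg$n_subjects
  set.seed(cfg$seed)
  fa_label <- sample(rep(skill_levels, length.out = n))
  wm_label <- sample(rep(skill_levels, length.out = n))
  score_in <- function(lab) {
    lo <- c(low = 0, moderate = 200, high = 400)[lab]
    hi <- c(low = 200, moderate = 400, high = 800)[lab]
    stats::runif(length(lab), lo, hi)
  }
  fa_score <- score_in(fa_label)
  wm_score <- score_in(wm_label)
  subj_seed <- sample.int(2147483646L, n)
  ids <- sprintf("S%03d", seq_len(n))
  recordings <- vector("list", n)
  for (i in seq_len(n)) {
    mult <- signatures$fa[fa_label[i], ] * signatures$wm[wm_label[i], ]
    recordings[[i]] <- .generate_eeg(cfg, mult, seed = subj_seed[i],
                                     subject_id = ids[i])
  }
  scores <- data.frame(subject_id = ids, fa_score = fa_score,
                       wm_score = wm_score, fa_label = fa_label,
                       wm_label = wm_label, stringsAsFactors = FALSE)
  list(recordings = recordings, scores = scores)
}
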