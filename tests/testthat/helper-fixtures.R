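# Shared fixtures, built once per test run and memoized.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env))
    assign(key, expr, envir = .fixture_env)
  get(key, envir = .fixture_env)
}

# small single-subject recording for fast unit tests
small_recording <- function(seed = 11, effect = 1, duration = 30,
                            artifact_rate = 0.8, dc_offset = 50) {
  cfg <- cohort_config(n_subjects = 3, duration_s = duration,
                       effect_size = effect, artifact_rate = artifact_rate,
                       dc_offset = dc_offset, seed = seed)
  generate_recording("moderate", cfg, class_signature("fa", effect),
                     seed = seed, subject_id = "S001")
}

# the standard 90-subject study cohort (60 s task), with combined features;
# reused by the classification and acceptance tests
study_cohort <- function(effect = 1, seed = 42) {
  key <- sprintf("cohort_%g_%d", effect, seed)
  memo(key, {
    cfg <- cohort_config(n_subjects = 90, duration_s = 60,
                         effect_size = effect, seed = seed)
    cohort <- generate_cohort(cfg)
    feats <- feature_table(cohort$recordings, "combined", pipeline_config())
    list(cohort = cohort, features = feats,
         X = as.matrix(feats[, -1, drop = FALSE]),
         y_fa = factor(cohort$scores$fa_label,
                       levels = c("low", "moderate", "high")),
         y_wm = factor(cohort$scores$wm_label,
                       levels = c("low", "moderate", "high")))
  })
}

# sinusoid helper
sine_wave <- function(freq, n = 1280, fs = 128, amp = 1, phase = 0, dc = 0) {
  dc + amp * sin(2 * pi * freq * (0:(n - 1)) / fs + phase)
}
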