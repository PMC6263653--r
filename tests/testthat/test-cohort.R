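test_that("score generator respects support and skew signs", {
  s_pos <- generate_scores(5000, "positive", seed = 1)
  s_neg <- generate_scores(5000, "negative", seed = 1)
  expect_true(all(s_pos >= 0 & s_pos <= 800))
  expect_true(all(s_neg >= 0 & s_neg <= 800))
  expect_gt(e1071::skewness(s_pos, type = 2), 0)
  expect_lt(e1071::skewness(s_neg, type = 2), 0)
  s_small <- generate_scores(200, "positive", seed = 7)
  expect_true(all(s_small >= 0 & s_small <= 800))
  expect_error(generate_scores(100, "sideways"), "skew")
})

test_that("zero effect size makes recordings label-independent", {
  cfg <- cohort_config(n_subjects = 3, duration_s = 10, seed = 3)
  sig0 <- class_signature("fa", effect_size = 0)
  r1 <- generate_recording("low", cfg, sig0, seed = 99)
  r2 <- generate_recording("high", cfg, sig0, seed = 99)
  expect_identical(r1$data, r2$data)
})

test_that("DC offset shifts the task-segment mean by its value", {
  cfg0 <- cohort_config(n_subjects = 3, duration_s = 10, dc_offset = 0,
                        seed = 3)
  cfg100 <- cohort_config(n_subjects = 3, duration_s = 10, dc_offset = 100,
                          seed = 3)
  sig <- class_signature("fa", 1)
  r0 <- generate_recording("low", cfg0, sig, seed = 21)
  r100 <- generate_recording("low", cfg100, sig, seed = 21)
  task0 <- split_baseline(r0)$task
  task100 <- split_baseline(r100)$task
  d <- mean(task100$data) - mean(task0$data)
  expect_lt(abs(d - 100), 5)
})

test_that("artifact-free recordings never trip the 3x mean-amplitude rule", {
  for (seed in c(5, 17)) {
    cfg <- cohort_config(n_subjects = 3, duration_s = 20, artifact_rate = 0,
                         dc_offset = 0, seed = seed)
    r <- generate_recording("moderate", cfg, seed = seed)
    thr <- 3 * rowMeans(abs(r$data))
    expect_equal(sum(abs(r$data) > thr), 0)
  }
})

test_that("planted spikes exceed the outlier threshold when rate > 0", {
  cfg <- cohort_config(n_subjects = 3, duration_s = 60, artifact_rate = 4,
                       seed = 5)
  r <- generate_recording("low", cfg, seed = 31)
  d <- remove_dc(r)
  thr <- 3 * rowMeans(abs(d$data))
  expect_gt(sum(abs(d$data) > thr), 0)
})

test_that("recording dimensions, baseline span and minimum-duration error", {
  cfg <- cohort_config(n_subjects = 3, duration_s = 10, baseline_s = 36,
                       seed = 2)
  r <- generate_recording("high", cfg, seed = 8)
  expect_equal(nrow(r$data), 14)
  expect_equal(ncol(r$data), (36 + 10) * 128)
  expect_equal(r$baseline_span, c(0L, 36L * 128L))
  cfg_short <- cohort_config(n_subjects = 3, duration_s = 1, seed = 2)
  expect_error(generate_recording("low", cfg_short, seed = 1),
               "at least")
})

test_that("cohorts are reproducible and carry consistent labels", {
  cfg <- cohort_config(n_subjects = 30, duration_s = 10, seed = 77)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1$scores, c2$scores)
  expect_identical(c1$recordings[[5]]$data, c2$recordings[[5]]$data)
  expect_length(c1$recordings, 30)
  expect_equal(nrow(c1$scores), 30)
  # labels match the scores' encoding and all classes are present per skill
  expect_equal(as.character(encode_score(c1$scores$fa_score)),
               c1$scores$fa_label)
  expect_equal(as.character(encode_score(c1$scores$wm_score)),
               c1$scores$wm_label)
  expect_setequal(unique(c1$scores$fa_label), c("low", "moderate", "high"))
  expect_setequal(unique(c1$scores$wm_label), c("low", "moderate", "high"))
})

test_that("background spectrum decays from theta to gamma (1/f shape)", {
  cfg <- cohort_config(n_subjects = 3, duration_s = 100, artifact_rate = 0,
                       dc_offset = 0, seed = 9)
  r <- generate_recording("low", cfg, class_signature("fa", 0), seed = 9)
  # strip the band oscillations: regenerate a background-only channel by
  # zeroing band RMS is internal, so instead test band-averaged *density*
  # of the averaged periodogram, which the 1/f background dominates only
  # at low frequency; use a pure-background synthesis via the internal
  # shape for a direct check
  set.seed(9)
  x <- eegcog:::.synth_shaped(100 * 128, 128, eegcog:::.shape_background)
  p <- avg_periodogram(x, 128)
  dens <- sapply(seq_len(nrow(eeg_bands)), function(i) {
    hi <- min(eeg_bands$high[i], 43)
    sel <- p$frequencies >= eeg_bands$low[i] & p$frequencies < hi
    mean(p$power[sel])
  })
  expect_true(all(diff(dens) < 0))
})

test_that("planted theta effect moves theta power in signature direction", {
  cfg <- cohort_config(n_subjects = 3, duration_s = 30, artifact_rate = 0,
                       dc_offset = 0, seed = 15)
  sig <- class_signature("fa", effect_size = 1.5)
  theta_rel <- function(label, seed) {
    r <- generate_recording(label, cfg, sig, seed = seed)
    seg <- split_baseline(r)
    p <- normalize_periodogram(avg_periodogram(seg$task$data[1, ], 128))
    band_powers(p)[["theta"]]
  }
  lo <- mean(sapply(1:8, function(s) theta_rel("low", 100 + s)))
  hi <- mean(sapply(1:8, function(s) theta_rel("high", 100 + s)))
  expect_gt(hi, lo)
})
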