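test_that("STFT segment counts follow the hop arithmetic", {
  x <- rnorm(1024)
  expect_equal(ncol(stft(x, 256, 0.5)$fft), 7)   # floor((1024-256)/128)+1
  expect_equal(ncol(stft(x, 256, 0)$fft), 4)     # disjoint tiling
  expect_error(stft(rnorm(100), 256), "at least 256")
})

test_that("a pure 10 Hz tone peaks at bin 20 in every Hann segment", {
  x <- sine_wave(10, n = 1024, amp = 5)
  st <- stft(x, 256, 0.5)
  for (s in seq_len(ncol(st$fft))) {
    p <- periodogram(st$fft[, s], 256, fs = 128)
    expect_equal(which.max(p$power) - 1, 20)  # 10 Hz at 0.5 Hz resolution
    expect_equal(p$frequencies[which.max(p$power)], 10)
  }
})

test_that("periodogram obeys Parseval's identity and |.|^2 homogeneity", {
  set.seed(12)
  x <- rnorm(64)
  p <- periodogram(stats::fft(x), 64, fs = 128)
  expect_equal(sum(p$power), sum(x^2), tolerance = 1e-12)
  p2 <- periodogram(stats::fft(2 * x), 64, fs = 128)
  expect_equal(p2$power, 4 * p$power, tolerance = 1e-12)
  z <- periodogram(stats::fft(rep(0, 64)), 64)
  expect_true(all(z$power == 0))
  expect_true(all(p$power >= 0))
  expect_true(all(p$frequencies >= 0 & p$frequencies <= 64))
})

test_that("normalized periodogram sums to one, preserves shape, is idempotent", {
  set.seed(13)
  p <- avg_periodogram(rnorm(2048), 128)
  np <- normalize_periodogram(p)
  expect_equal(sum(np$power), 1, tolerance = 1e-9)
  expect_equal(np$power / np$power[10], p$power / p$power[10],
               tolerance = 1e-12)
  expect_equal(normalize_periodogram(np)$power, np$power, tolerance = 1e-12)
  # two-bin worked example
  toy <- structure(list(frequencies = c(1, 2), power = c(3, 1),
                        normalization = "raw", N = 4, fs = 8),
                   class = "eeg_spectrum")
  expect_equal(normalize_periodogram(toy)$power, c(0.75, 0.25))
  toy$power <- c(0, 0)
  expect_error(normalize_periodogram(toy), "all-zero")
})

test_that("averaged Hann periodogram matches an independent DFT implementation", {
  # textbook averaged-modified-periodogram, via an explicit DFT matrix
  set.seed(21)
  fs <- 128
  x <- rnorm(10 * fs)
  N <- 256
  hop <- 128
  w <- 0.5 * (1 - cos(2 * pi * (0:(N - 1)) / N))
  k <- 0:(N - 1)
  W <- exp(-2i * pi * outer(k, k) / N)
  nseg <- floor((length(x) - N) / hop) + 1
  acc <- numeric(N / 2 + 1)
  for (s in seq_len(nseg)) {
    seg <- w * x[((s - 1) * hop + 1):((s - 1) * hop + N)]
    X <- as.vector(W %*% seg)
    p2 <- Mod(X)^2 / N
    one <- p2[1:(N / 2 + 1)]
    one[2:(N / 2)] <- 2 * one[2:(N / 2)]
    acc <- acc + one
  }
  oracle <- acc / nseg
  got <- avg_periodogram(x, fs, N, 0.5)
  expect_equal(got$n_segments, nseg)
  expect_lt(max(abs(got$power - oracle)) / max(oracle), 1e-6)
})

test_that("band powers: tone concentration and flat-noise proportionality", {
  x <- sine_wave(10, n = 4096, amp = 30)
  p <- normalize_periodogram(avg_periodogram(x, 128))
  bp <- band_powers(p)
  expect_gte(bp[["alpha"]], 0.95)
  expect_lte(bp[["theta"]] + bp[["beta"]] + bp[["gamma"]], 0.05)
  expect_true(all(bp >= 0 & bp <= 1))

  set.seed(30)
  pw <- normalize_periodogram(avg_periodogram(rnorm(1e5), 128))
  bw <- band_powers(pw)
  widths <- c(theta = 4, alpha = 4, beta = 18, gamma = 13)
  ratio <- bw / sum(bw)
  expect_equal(unname(ratio), unname(widths / sum(widths)), tolerance = 0.1)

  bad <- eeg_bands
  bad$high[4] <- 200
  bad$low[4] <- 150
  expect_error(band_powers(pw, bad), "fs/2")
})

test_that("dB normalization hits the 0 / 10 / 3.0103 dB anchors", {
  expect_equal(db_normalize(5, 5), 0)
  expect_equal(db_normalize(50, 5), 10)
  expect_equal(db_normalize(10, 5), 3.0103, tolerance = 1e-4)
  expect_equal(db_normalize(c(1, 2, 4), c(1, 1, 1)),
               c(0, 10 * log10(2), 10 * log10(4)))
  expect_error(db_normalize(1, 0), "strictly positive")
  expect_error(db_normalize(-1, 1), "non-negative")
})

test_that("spectral rows: 70 features, identical-segment null, planted ratio", {
  r <- small_recording(seed = 29, duration = 20, artifact_rate = 0)
  seg <- split_baseline(preprocess_variant(r, "nodc")$recording)
  row <- spectral_feature_row(seg$task, seg$baseline)
  expect_length(row, 70)
  expect_true(all(startsWith(names(row)[1:5], "AF3_")))

  # baseline == task: every dB band feature is exactly 0
  null_row <- spectral_feature_row(seg$task, seg$task)
  dbs <- null_row[grepl("_db$", names(null_row))]
  expect_equal(max(abs(dbs)), 0, tolerance = 1e-9)

  # plant a 3x theta-power increase: theta feature ~ 10*log10(3) dB
  set.seed(31)
  n <- 30 * 128
  theta <- 10 * eegcog:::.synth_shaped(n, 128, eegcog:::.shape_band(4, 8))
  rest <- 8 * eegcog:::.synth_shaped(n, 128, eegcog:::.shape_band(12, 30))
  base <- eeg_recording(matrix(theta + rest, 1, n, byrow = TRUE), 128,
                        channel_labels = "AF3")
  task <- eeg_recording(matrix(sqrt(3) * theta + rest, 1, n, byrow = TRUE),
                        128, channel_labels = "AF3")
  row3 <- spectral_feature_row(task, base)
  expect_equal(unname(row3["AF3_theta_db"]), 10 * log10(3), tolerance = 0.3)

  # relative variant sums the four bands to at most 1
  rel <- spectral_feature_row(seg$task, normalize_db = FALSE)
  rels <- rel[grepl("_rel$", names(rel))]
  expect_true(all(rels >= 0 & rels <= 1))
  per_ch <- tapply(rels, rep(1:14, each = 4), sum)
  expect_true(all(per_ch <= 1 + 1e-9))

  short <- eeg_recording(matrix(rnorm(100), 1, 100), 128,
                         channel_labels = "AF3")
  expect_error(spectral_feature_row(seg$task, short), "baseline shorter")
})
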