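# Independent brute-force evaluation of the Hjorth definitions on a vector,
# written directly from the variance-ratio formulas with explicit forward
# differences.
hjorth_oracle <- function(x) {
  fd <- function(v) v[-1] - v[-length(v)]
  mob <- function(v) sqrt(stats::var(fd(v)) / stats::var(v))
  c(mobility = mob(x), complexity = mob(fd(x)) / mob(x))
}

test_that("Hjorth parameters match brute-force evaluation on the worked vector", {
  x <- c(1, 2, 3, 2, 1)
  got <- hjorth_parameters(x)
  expect_equal(got, hjorth_oracle(x), tolerance = 1e-9)
  expect_equal(unname(got["mobility"]), 1.3801311, tolerance = 1e-6)
  expect_equal(unname(got["complexity"]), 0.7245688, tolerance = 1e-6)
  set.seed(2)
  for (i in 1:5) {
    v <- rnorm(50)
    expect_equal(hjorth_parameters(v), hjorth_oracle(v), tolerance = 1e-9)
  }
})

test_that("Hjorth parameters are amplitude- and phase-invariant for sinusoids", {
  for (f in c(4, 10, 20)) {
    base <- hjorth_parameters(sine_wave(f, n = 1280))
    for (amp in c(0.5, 7, 120)) {
      got <- hjorth_parameters(sine_wave(f, n = 1280, amp = amp))
      expect_equal(got, base, tolerance = 1e-9)
    }
    # phase invariance is exact only over whole periods of the difference
    # series, which is one sample short; mobility agrees to ~1e-3
    shifted <- hjorth_parameters(sine_wave(f, n = 1280, phase = 1.1))
    expect_equal(shifted[["mobility"]], base[["mobility"]],
                 tolerance = 2e-3)
  }
  # random signals: pure scaling leaves both parameters unchanged
  set.seed(6)
  v <- rnorm(200)
  expect_equal(hjorth_parameters(3.7 * v), hjorth_parameters(v),
               tolerance = 1e-9)
})

test_that("Hjorth error paths: zero variance and linear ramps", {
  expect_error(hjorth_parameters(rep(1, 10)), "zero variance")
  # ramp: constant first difference => zero mobility => complexity undefined
  expect_error(hjorth_parameters(2 * (1:20)), "complexity")
  expect_error(hjorth_parameters(c(1, 2)), "at least 3")
})

test_that("Shapiro-Wilk wrapper is calibrated and bounded", {
  set.seed(10)
  p_norm <- replicate(200, shapiro_wilk(rnorm(500))["p"])
  expect_gt(median(p_norm), 0.3)
  expect_lt(median(p_norm), 0.7)
  p_unif <- replicate(200, shapiro_wilk(runif(500))["p"])
  expect_gte(mean(p_unif < 0.01), 0.95)
  w <- shapiro_wilk(rnorm(5000))
  expect_lte(w[["W"]], 1)
  expect_gte(w[["p"]], 0)
  expect_lte(w[["p"]], 1)
  # long series are handled through deterministic subsampling
  long <- sin(1:20000) + rnorm(20000)
  expect_identical(shapiro_wilk(long), shapiro_wilk(long))
  expect_error(shapiro_wilk(rep(3, 100)), "constant")
})

test_that("time feature rows have 210 stable channel-major names", {
  r <- small_recording(seed = 23, duration = 10)
  seg <- split_baseline(r)
  row1 <- time_feature_row(seg$task)
  row2 <- time_feature_row(seg$task)
  expect_length(row1, 210)
  expect_identical(row1, row2)
  expect_identical(names(row1)[1:3], c("AF3_min", "AF3_max", "AF3_mean"))
  # channel-major: first 15 names all AF3, next 15 all AF4
  expect_true(all(startsWith(names(row1)[1:15], "AF3_")))
  expect_true(all(startsWith(names(row1)[16:30], "AF4_")))
})

test_that("time features satisfy their internal consistency invariants", {
  set.seed(3)
  for (i in 1:5) {
    n <- sample(500:2000, 1)
    x <- rnorm(n, mean = runif(1, -40, 60), sd = runif(1, 0.5, 30))
    f <- eegcog:::.channel_time_features(x, "CH")
    expect_lte(f[["q25"]], f[["q50"]])
    expect_lte(f[["q50"]], f[["q75"]])
    expect_lte(f[["min"]], f[["q25"]])
    expect_lte(f[["q75"]], f[["max"]])
    expect_equal(f[["std"]], sqrt(f[["variance"]]))
    expect_equal(f[["coefficient_of_variation"]], f[["std"]] / f[["mean"]])
    expect_gte(f[["shapiro_p"]], 0)
    expect_lte(f[["shapiro_p"]], 1)
  }
})

test_that("time features match distributional expectations on N(0,1) input", {
  set.seed(14)
  x <- rnorm(1e4)
  x <- x + 1e-9  # guard the exact-zero-mean error path, mean is still ~0
  f <- eegcog:::.channel_time_features(x, "CH")
  expect_lt(abs(f[["mean"]]), 0.05)
  expect_lt(abs(f[["variance"]] - 1), 0.05)
  expect_lt(abs(f[["kurtosis"]]), 0.2)
  expect_lt(abs(f[["skewness"]]), 0.1)
})

test_that("an exactly zero-mean channel triggers the CoV error path", {
  x <- rep(c(-1, 2, -1), 100)
  expect_equal(mean(x), 0)
  expect_error(eegcog:::.channel_time_features(x, "AF3"),
               "coefficient of variation")
})

test_that("constant channels are reported by name", {
  d <- rbind(rnorm(300), rep(1, 300))
  rec <- eeg_recording(d, 128, channel_labels = c("AF3", "AF4"))
  expect_error(time_feature_row(rec), "AF4")
})
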