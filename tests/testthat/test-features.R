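test_that("band_power returns one nonnegative value per band", {
  x <- sin(2 * pi * 10 * (0:399) / 100)
  bp <- band_power(x, fs = 100)
  expect_length(bp, 5L)
  expect_true(all(bp >= 0))

  expect_equal(band_power(rep(0, 400), 100), rep(0, 5))
})

test_that("a pure 10 Hz tone concentrates in the 8-12 Hz band", {
  x <- sin(2 * pi * 10 * (0:399) / 100)
  for (m in c("welch", "periodogram")) {
    bp <- band_power(x, 100, method = m)
    expect_gt(bp[3] / sum(bp), 0.95)
  }
})

test_that("band power scales quadratically with amplitude", {
  set.seed(1)
  x <- rnorm(400)
  expect_equal(band_power(3 * x, 100), 9 * band_power(x, 100),
               tolerance = 1e-10)
})

test_that("band_power rejects invalid bands and short signals", {
  expect_error(band_power(rnorm(400), 100, bands = cbind(10, 60)),
               "Nyquist")
  expect_error(band_power(rnorm(50), 100), "window length")
})

test_that("time_stats matches hand-computed values", {
  expect_equal(unname(time_stats(rep(3, 10))), c(3, 0, 0, 0))
  ramp <- 0.7 * (0:19)
  ts <- time_stats(ramp)
  expect_equal(unname(ts[3]), 0.7)
  expect_equal(unname(ts[4]), 0, tolerance = 1e-14)
  alt <- c(1, -1, 1, -1)
  ts <- time_stats(alt)
  expect_equal(unname(ts[c(1, 3, 4)]), c(0, 2, 4))
  expect_error(time_stats(c(1, 2)), "at least 3")
})

test_that("a constant shift moves only the mean", {
  set.seed(2)
  x <- rnorm(100)
  a <- time_stats(x)
  b <- time_stats(x + 5)
  expect_equal(unname(b[1] - a[1]), 5, tolerance = 1e-12)
  expect_equal(unname(b[2:4]), unname(a[2:4]), tolerance = 1e-12)
})

test_that("AR coefficients recover a simulated AR(1) process", {
  set.seed(3)
  x <- as.numeric(stats::arima.sim(list(ar = 0.5), 10000))
  for (m in c("burg", "yule_walker")) {
    a <- ar_coefficients(x, 6, m)
    expect_length(a, 6L)
    expect_lt(abs(a[1] - 0.5), 0.05)
    expect_true(all(abs(a[-1]) < 0.1))
  }
  w <- rnorm(10000)
  expect_true(all(abs(ar_coefficients(w, 6)) < 0.05))
})

test_that("AR estimation rejects degenerate input", {
  expect_error(ar_coefficients(rep(1, 100), 6), "constant")
  expect_error(ar_coefficients(rnorm(10), 6), "too short")
})

test_that("Fourier resampling has the contracted length and preserves DC", {
  x <- matrix(sin(2 * pi * 7 * (0:3999) / 1000), 1)
  y <- resample_trial(x, 1000, 100)
  expect_equal(ncol(y), 400L)
  # the 7 Hz tone survives the 1000 -> 100 Hz decimation
  bp <- band_power(drop(y), 100)
  expect_gt(bp[2] / sum(bp), 0.95)

  const <- matrix(2.5, 2, 400)
  expect_equal(resample_trial(const, 1000, 100), matrix(2.5, 2, 40),
               tolerance = 1e-12)
  expect_identical(resample_trial(const, 100, 100), const)
  expect_error(resample_trial(const, 100, 200), "upsampling")
})

test_that("fused extraction yields 70 contiguous columns per channel", {
  ts <- gen_eeg_trials(eeg_sim_spec(n_channels = 3, n_trials_per_class = 2,
                                    active_channels = 1L, seed = 5))
  ff <- extract_fused(ts)
  expect_equal(ff$d, 70L)
  expect_equal(dim(ff$values), c(4L, 210L))
  expect_equal(ff$group_index, rep(1:3, each = 70))
  expect_true(all(is.finite(ff$values)))
  # group blocks contiguous and exhaustive
  r <- rle(ff$group_index)
  expect_equal(r$lengths, rep(70L, 3))

  one <- trial_set(lapply(ts$trials, function(m) m[1, , drop = FALSE]),
                   ts$labels, ts$fs)
  f1 <- extract_fused(one)
  expect_equal(ncol(f1$values), 70L)
  expect_equal(unique(f1$group_index), 1L)
})

test_that("extraction errors carry trial and channel context", {
  ts <- gen_eeg_trials(eeg_sim_spec(n_channels = 2, n_trials_per_class = 2,
                                    active_channels = 1L, seed = 6))
  ts$trials[[2]][2, ] <- 1            # constant channel breaks the AR fit
  expect_error(extract_fused(ts), "trial 2, channel 2")
  expect_error(trial_set(list(), integer(0), 100), "non-empty")
})

test_that("the literal terminal wavelet convention gives 35 dimensions", {
  cfg <- feature_config(wavelet_convention = "terminal")
  expect_equal(cfg$d, 5L + 4L + 6L + 35L)
  x <- sin(2 * pi * 5 * (0:399) / 100) + 0.1 * rnorm(400)
  expect_length(wavelet_features(x, convention = "terminal"), 35L)
})
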