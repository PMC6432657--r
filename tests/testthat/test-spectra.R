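test_that("Burg recursion recovers AR coefficients (long-simulation oracle)", {
  set.seed(42)
  # white noise: no structure, all coefficients small
  w <- rnorm(1e4)
  expect_lt(max(abs(burg_fit(w, 4)$coef)), 0.1)
  # AR(1) phi = 0.8
  x <- as.numeric(arima.sim(list(ar = 0.8), 1e5))
  m1 <- burg_fit(x, 1)
  expect_equal(m1$coef, 0.8, tolerance = 0.01)
  # agreement with the independent stats::ar.burg implementation
  y <- as.numeric(arima.sim(list(ar = c(0.5, -0.3)), 2000))
  m2 <- burg_fit(y, 2)
  ref <- ar.burg(y, aic = FALSE, order.max = 2, demean = TRUE)
  expect_equal(m2$coef, as.numeric(ref$ar), tolerance = 1e-8)
  expect_error(burg_fit(y, 2000), "P")
  expect_error(burg_fit(rep(1, 50), 3), "zero-variance")
})

test_that("AR spectra have the stated shape, positivity and total power", {
  flat <- structure(list(order = 1, coef = 0, noise_variance = 2),
                    class = "ar_model")
  ps <- ar_psd(flat, 10, 256)
  expect_equal(ps$power, rep(0.2, 256), tolerance = 1e-12)
  # AR(2) with complex poles at 1 Hz (rate 10): peak within one grid bin
  r <- 0.95; th <- 2 * pi * 1 / 10
  phi <- c(2 * r * cos(th), -r^2)
  m <- structure(list(order = 2, coef = phi, noise_variance = 1),
                 class = "ar_model")
  ps <- ar_psd(m, 10, 2049)
  expect_true(all(ps$power > 0))
  expect_lt(abs(ps$freqs[which.max(ps$power)] - 1), 2 * diff(ps$freqs[1:2]))
  # Parseval: integral over [0, Nyquist] ~ half the process variance (AR(1))
  set.seed(1)
  x <- as.numeric(arima.sim(list(ar = 0.6), 1e5))
  mf <- burg_fit(x, 1)
  psf <- ar_psd(mf, 1, 4097)
  integral <- mean(psf$power) * 0.5  # grid mean x bandwidth
  expect_equal(2 * integral, var(x), tolerance = 0.05 * var(x))
})

test_that("spectrogram window arithmetic and degenerate inputs", {
  fx <- fix_baseline_11()
  # 300 s at 10 Hz, 12.8 s windows, 50% overlap -> 45 full windows
  expect_equal(length(fx$spec$window_times), 45L)
  expect_true(all(diff(fx$spec$window_times) > 0))
  expect_true(all(fx$spec$power >= 0))
  expect_error(spectrogram(ppg_ts(rnorm(50), 10)), "shorter")
  # concatenation equals concatenated spectrograms for aligned segments
  x1 <- fix_baseline_11()$cond$samples[1:1280]
  x2 <- fix_baseline_11()$cond$samples[1281:2560]
  s12 <- spectrogram(ppg_ts(c(x1, x2), 10), overlap = 0, n_freq = 257)
  s1 <- spectrogram(ppg_ts(x1, 10), overlap = 0, n_freq = 257)
  s2 <- spectrogram(ppg_ts(x2, 10), overlap = 0, n_freq = 257)
  expect_equal(s12$power, cbind(s1$power, s2$power), tolerance = 1e-10)
})

test_that("peak tracking finds the programmed rhythm and respects the band", {
  fx <- fix_baseline_11()
  tr <- fx$track
  truth <- approx((seq_along(fx$sim$truth$f_heart_inst) - 1) / 500,
                  fx$sim$truth$f_heart_inst, tr$time_s)$y
  # no harmonic jumps; peak follows the wandering truth closely
  expect_true(all(abs(tr$peak_freq_hz - truth) < 0.06))
  expect_gt(mean(abs(tr$peak_freq_hz - truth) <= 0.02), 0.9)
  # median of the track sits at the programmed frequency within half the
  # method's intrinsic resolution (1 / window)
  expect_lt(abs(baseline_median(tr) - 1.1), 0.5 / 12.8)
  # band restriction: searching (1.5, 2.5) must return in-band frequencies
  tr_hi <- track_peak(fx$spec, c(1.5, 2.5))
  expect_true(all(tr_hi$peak_freq_hz >= 1.5 & tr_hi$peak_freq_hz <= 2.5))
  expect_error(track_peak(fx$spec, c(6, 7)), "band")
  # two-band selection: with rhythms at 0.5 and 1.2 Hz, band (0.9, 2)
  # returns the 1.2 Hz band
  two <- ppg_ts(sin(2 * pi * 0.5 * (0:2999) / 10) +
                0.8 * sin(2 * pi * 1.2 * (0:2999) / 10) +
                rnorm(3000, 0, 0.1), 10)
  tr2 <- track_peak(spectrogram(two), c(0.9, 2))
  expect_lt(abs(median(tr2$peak_freq_hz) - 1.2), 0.05)
})

test_that("population histogram normalization sums to at most one", {
  # one animal, all mass in one bin
  h1 <- population_histogram(list(rep(1.05, 20)), bin_width = 0.1)
  expect_equal(sum(h1$height), 1)
  expect_equal(max(h1$height), 1)
  # two animals with disjoint single bins -> two bars of height 0.5
  h2 <- population_histogram(list(rep(0.55, 5), rep(1.25, 9)), bin_width = 0.1)
  expect_equal(sort(h2$height[h2$height > 0]), c(0.5, 0.5))
  # out-of-range mass reduces the total below 1
  h3 <- population_histogram(list(c(rep(1, 9), 9.9)), bin_width = 0.1)
  expect_equal(sum(h3$height), 0.9)
  # many synthetic animals: total mass <= 1 within 1e-12
  set.seed(3)
  many <- replicate(49, runif(40, 0, 2.4), simplify = FALSE)
  h4 <- population_histogram(many, bin_width = 0.1)
  expect_lte(sum(h4$height), 1 + 1e-12)
  expect_gt(sum(h4$height), 0.99)
})
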