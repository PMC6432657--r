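test_that("DPSS tapers are orthonormal with ordered concentrations", {
  tp <- dpss_tapers(512, 10, 19)
  G <- crossprod(tp$tapers)
  expect_lt(max(abs(G - diag(19))), 1e-8)
  expect_true(all(diff(tp$lambda) < 1e-10)) # non-increasing
  expect_true(all(tp$lambda > 0 & tp$lambda < 1 + 1e-12))
  # with K = 2NW - 1 = 19 the last taper is still usable
  expect_gt(tp$lambda[19], 0.5)
  expect_error(dpss_tapers(512, 10, 20), "2\\*NW - 1")
})

test_that("the theoretical coherence threshold matches its closed form", {
  expect_equal(coherence_threshold(0.05, 19, 1),
               sqrt(1 - 0.05^(1 / 18)), tolerance = 1e-12)
  expect_equal(coherence_threshold(0.05, 19, 1), 0.391557, tolerance = 1e-5)
  # no-confidence limit
  expect_lt(coherence_threshold(1 - 1e-12, 19, 1), 1e-5)
  # monotone increasing in the Bonferroni count, decreasing in K
  ns <- c(1, 10, 100, 1000)
  expect_true(all(diff(sapply(ns, function(n)
    coherence_threshold(0.05, 19, n))) > 0))
  ks <- c(5, 10, 19, 29)
  expect_true(all(diff(sapply(ks, function(k)
    coherence_threshold(0.05, k, 1))) < 0))
  expect_error(coherence_threshold(0.05, 1, 1), "dof")
})

test_that("self-coherence is one at zero phase; magnitude bounded in [0,1]", {
  set.seed(4)
  x <- ppg_ts(rnorm(3000), 10)
  res <- mt_coherence(x, x, window_s = 60, step_s = 30, nw = 4, k = 7)
  m <- res$magnitude[is.finite(res$magnitude)]
  expect_true(all(m >= 0 & m <= 1 + 1e-9))
  expect_true(all(m > 1 - 1e-6))
  ph <- res$phase_deg[is.finite(res$phase_deg)]
  expect_true(all(pmin(ph, 360 - ph) < 1e-4))
})

test_that("phase convention: delaying y by tau gives +360 f tau degrees", {
  set.seed(6)
  rate <- 10
  n <- 6000
  base <- as.numeric(stats::filter(rnorm(n + 50), rep(1, 8) / 8, sides = 1))
  base[is.na(base)] <- 0
  tau_samp <- 3  # 0.3 s
  x <- ppg_ts(base[51:(n + 50)], rate)
  y <- ppg_ts(base[(51 - tau_samp):(n + 50 - tau_samp)], rate)
  res <- mt_coherence(x, y, window_s = 120, step_s = 60, nw = 10, k = 19,
                      band = c(0.2, 2.5))
  sel <- which(res$freqs > 0.4 & res$freqs < 1.2)
  expected <- (360 * res$freqs[sel] * 0.3) %% 360
  got <- res$phase_deg[sel, 3]
  dd <- abs(got - expected) %% 360
  expect_lt(max(pmin(dd, 360 - dd)), 15)
})

test_that("coherence magnitude is invariant to channel rescaling", {
  fx <- fix_coupled()
  r1 <- mt_coherence(fx$heart, fx$pyloric, window_s = 120, step_s = 60)
  y2 <- ppg_ts(7.3 * fx$pyloric$samples, 10)
  x2 <- ppg_ts(0.2 * fx$heart$samples, 10)
  r2 <- mt_coherence(x2, y2, window_s = 120, step_s = 60)
  expect_equal(r1$magnitude, r2$magnitude, tolerance = 1e-9)
})

test_that("a coupled pair is flagged coherent with the programmed phase", {
  fx <- fix_coupled()
  res <- mt_coherence(fx$heart, fx$pyloric)
  C <- coherence_threshold(0.05, 19, length(res$window_times))
  sm <- coherence_summary(res, C)
  expect_true(sm$is_coherent_dataset)
  expect_gt(sm$fraction_significant, 0.9)
  expect_lt(abs(sm$median_phase_deg - 190), 10)
  # the peak-coherence frequency sits at the heart rhythm
  expect_lt(abs(median(res$peaks$peak_freq_hz) - 1.1), 0.15)
})

test_that("independent channels fall below threshold (null calibration)", {
  set.seed(10)
  # ~1000 heavily stepped windows of independent white noise
  n <- 1200 + 999 * 12
  x <- ppg_ts(rnorm(n), 10)
  y <- ppg_ts(rnorm(n), 10)
  res <- mt_coherence(x, y, window_s = 120, step_s = 1.2, nw = 10, k = 19)
  # per-frequency exceedance of the alpha-level threshold is ~alpha
  C1 <- coherence_threshold(0.05, 19, 1)
  sel <- which(res$freqs > 0.3 & res$freqs < 4.7)
  exceed <- mean(res$magnitude[sel[seq(1, length(sel), by = 40)], ] > C1)
  expect_lt(exceed, 1.5 * 0.05)
  # Bonferroni-corrected peak threshold keeps most windows sub-threshold
  Cn <- coherence_threshold(0.05, 19, length(res$window_times))
  expect_gt(mean(res$peaks$peak_coherence < Cn), 0.9)
  sm <- coherence_summary(res, Cn)
  expect_false(sm$is_coherent_dataset)
})

test_that("cross/auto-correlation have the stated fixed points", {
  fx <- fix_coupled()
  ac <- xcorr_fun(fx$heart, max_lag_s = 3)
  expect_equal(ac$corr[ac$lag_s == 0], 1, tolerance = 1e-9)
  # periodic signal: autocorrelation peaks again near +/- one period
  pos <- ac[ac$lag_s > 0.6, ]
  expect_lt(abs(pos$lag_s[which.max(pos$corr)] - 1 / 1.1), 0.1)
  # near-antiphase coupling (190 deg) gives a deep trough near zero lag
  cc <- xcorr_fun(fx$heart, fx$pyloric, max_lag_s = 0.3)
  trough <- cc$lag_s[which.min(cc$corr)]
  expect_lt(abs(trough), 0.25)
  expect_lt(min(cc$corr), -0.2)
  expect_error(xcorr_fun(ppg_ts(rep(1, 100), 10)), "zero-variance")
})

test_that("circular median handles the wraparound", {
  expect_equal(circular_median_deg(c(350, 355, 5, 10, 15)), 5)
  expect_equal(circular_median_deg(c(188, 190, 192)), 190)
  expect_true(is.na(circular_median_deg(numeric(0))))
})
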