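test_that("log-RMS bout feature has the stated arithmetic", {
  s <- sine_ts(1, rate = 100, dur = 60)
  f1 <- bout_feature(s, 2, 1)
  expect_lt(diff(range(f1$feature)), 1e-6)
  # amplitude halved in the second half: feature drops by log 2
  half <- ppg_ts(c(s$samples[1:3000], 0.5 * s$samples[3001:6000]), 100)
  f2 <- bout_feature(half, 2, 1)
  expect_equal(mean(f2$feature[1:20]) - mean(f2$feature[40:58]), log(2),
               tolerance = 1e-6)
  expect_error(bout_feature(sine_ts(1, 100, 1), 2, 1), "longer")
  # synthetic bout recording: bimodal feature, modes separated by
  # |log bout_amp_factor|
  sim <- gen_baseline(synth_params(bouts = TRUE, bout_mean_active_s = 60,
                                   bout_mean_inhib_s = 40,
                                   bout_amp_factor = 0.1, noise_sd = 0,
                                   duration_s = 1200, seed = 14),
                      channels = "heart")
  fb <- bout_feature(preprocess_ts(sim$recording$heart, run_config()))
  km <- sort(kmeans(fb$feature, 2, nstart = 5)$centers[, 1])
  expect_equal(unname(diff(km)), abs(log(0.1)), tolerance = 0.25)
})

test_that("Baum-Welch recovers a known two-state Gaussian HMM", {
  set.seed(33)
  A <- matrix(c(0.98, 0.02, 0.05, 0.95), 2, 2, byrow = TRUE)
  n <- 5000
  st <- integer(n); st[1] <- 1L
  for (t in 2:n) st[t] <- sample(1:2, 1, prob = A[st[t - 1], ])
  obs <- rnorm(n, mean = c(1, -1)[st], sd = 0.3)
  fit <- baum_welch(obs)
  ord <- order(fit$means, decreasing = TRUE)  # state with mean +1 first
  expect_equal(fit$means[ord], c(1, -1), tolerance = 0.05)
  expect_equal(fit$transition[ord[1], ord[1]], 0.98, tolerance = 0.02)
  expect_equal(fit$transition[ord[2], ord[2]], 0.95, tolerance = 0.02)
  # log-likelihood is non-decreasing on every iteration
  tr <- attr(fit, "loglik_trace")
  expect_true(all(diff(tr) >= -1e-8 * abs(tr[-length(tr)])))
  # decoding accuracy on well-separated data
  dec <- decode_states(fit, obs)
  truth01 <- ifelse(st == 2L, 0L, 1L)  # true state 2 has the lower mean
  expect_gt(mean(dec$state == truth01), 0.99)
  # posteriors normalized
  expect_true(all(dec$posterior_inhib >= 0 & dec$posterior_inhib <= 1))
})

test_that("EM parameter recovery is stable over seeded replicates", {
  errs <- sapply(1:20, function(s) {
    set.seed(1000 + s)
    A <- matrix(c(0.98, 0.02, 0.05, 0.95), 2, 2, byrow = TRUE)
    n <- 2000
    st <- integer(n); st[1] <- 1L
    for (t in 2:n) st[t] <- sample(1:2, 1, prob = A[st[t - 1], ])
    obs <- rnorm(n, mean = c(1, -1)[st], sd = 0.3)
    fit <- baum_welch(obs)
    lo <- which.min(fit$means)
    abs(fit$transition[lo, lo] - 0.95)
  })
  expect_lt(mean(errs), 0.03)
})

test_that("decoding is invariant to affine feature rescaling", {
  set.seed(7)
  obs <- c(rnorm(300, 0, 0.2), rnorm(200, 2, 0.2), rnorm(300, 0, 0.2))
  d1 <- decode_states(baum_welch(obs), obs)
  obs2 <- 5 * obs - 3
  d2 <- decode_states(baum_welch(obs2), obs2)
  expect_identical(d1$state, d2$state)
})

test_that("single-regime data decodes to a constant all-active path", {
  set.seed(2)
  obs <- rnorm(500, 0, 0.5)
  fit <- baum_welch(obs)
  dec <- decode_states(fit, obs)
  expect_true(all(dec$state == 1L))
  # the guard can be disabled
  dec2 <- decode_states(fit, obs, check_one_state = FALSE)
  expect_true(any(dec2$state == 0L))
  expect_error(baum_welch(rep(1, 100)), "degenerate")
})

test_that("bout tables tile the record and run-length encode correctly", {
  states <- data.frame(time_s = 0:5, state = c(1L, 1L, 0L, 0L, 0L, 1L),
                       posterior_inhib = rep(0.5, 6))
  attr(states, "step_s") <- 1
  bd <- bout_durations(states)
  expect_equal(bd$bouts$state, c(1L, 0L, 1L))
  expect_equal(bd$bouts$duration_s, c(2, 3, 1))
  expect_equal(sum(bd$bouts$duration_s), 6)
  expect_true(all(diff(bd$bouts$start_s) > 0))
  # adjacent rows alternate state
  expect_true(all(diff(bd$bouts$state) != 0))
  # minimum-duration filter merges short runs
  states2 <- data.frame(time_s = 0:9,
                        state = c(1L, 1L, 1L, 0L, 1L, 1L, 0L, 0L, 0L, 1L),
                        posterior_inhib = rep(0.5, 10))
  attr(states2, "step_s") <- 1
  bd2 <- bout_durations(states2, min_duration_s = 2)
  expect_equal(bd2$bouts$state, c(1L, 0L, 1L))
  expect_equal(sum(bd2$bouts$duration_s), 10)
})

test_that("the full bout pipeline recovers dwell statistics on a 2 h record", {
  sim <- gen_baseline(synth_params(f_heart = 1.5, bouts = TRUE,
                                   bout_mean_active_s = 120,
                                   bout_mean_inhib_s = 30,
                                   bout_amp_factor = 0.1,
                                   duration_s = 7200, seed = 17),
                      channels = "heart")
  cond <- preprocess_ts(sim$recording$heart, run_config())
  feats <- bout_feature(cond)
  model <- baum_welch(feats)
  dec <- decode_states(model, feats)
  bd <- bout_durations(dec)
  segs <- sim$truth$bout_segments
  true_mean <- with(segs, mean(end_s[state == 0] - start_s[state == 0]))
  rec_mean <- bd$summary$mean_s[bd$summary$state == 0]
  expect_lt(abs(rec_mean - true_mean) / true_mean, 0.15)
  # decoded state path matches the ground truth at feature times
  st_true <- approx((seq_along(sim$truth$state_sequence) - 1) / 500,
                    sim$truth$state_sequence, dec$time_s,
                    method = "constant")$y
  expect_gt(mean(st_true == dec$state), 0.95)
})
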