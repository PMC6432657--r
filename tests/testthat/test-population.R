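test_that("Pearson correlation fixed points and errors", {
  x <- c(0.3, 0.9, 1.4, 2.0, 0.7)
  expect_equal(pearson_cor(x, x)$r, 1)
  expect_equal(pearson_cor(x, -x)$r, -1)
  expect_error(pearson_cor(x, rep(1, 5)), "zero-variance")
  expect_error(pearson_cor(1:2, 1:2), "n >= 3")
})

test_that("population generator + Pearson reproduce the calibrated correlation", {
  rs <- sapply(1:200, function(i) {
    d <- gen_population(29, 0.61, seed = 4000 + i)
    pearson_cor(d$f_heart, d$f_pyloric)$r
  })
  expect_lt(abs(mean(rs) - 0.61), 0.05)
})

test_that("one-way ANOVA matches hand-computed sums of squares and F = t^2", {
  # identical groups: F = 0, p = 1
  same <- one_way_anova(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(same$F, 0)
  expect_equal(same$p, 1)
  # {1,2,3} vs {4,5,6}: SSB = 13.5, MSW = 1 -> F = 13.5 on (1, 4) dof
  a <- one_way_anova(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(a$F, 13.5, tolerance = 1e-12)
  expect_equal(a$df, c(1, 4))
  # two-group ANOVA equals the squared equal-variance t statistic
  set.seed(15)
  for (i in 1:5) {
    g1 <- rnorm(8); g2 <- rnorm(11, 0.5)
    f <- one_way_anova(list(g1, g2))
    tt <- t.test(g1, g2, var.equal = TRUE)
    expect_equal(f$F, unname(tt$statistic)^2, tolerance = 1e-9)
    expect_equal(f$p, tt$p.value, tolerance = 1e-9)
  }
  expect_error(one_way_anova(list(1:3)), "2 groups")
  expect_error(one_way_anova(list(1:3, 2)), "n >= 2")
})

test_that("ANOVA separates critical-temperature groups at the observed effect size", {
  # groups drawn at the reported heart/pyloric means and sds (n = 12 vs 9)
  hits <- sapply(1:200, function(s) {
    set.seed(s)
    h <- rnorm(12, 25.0, 1.62)
    p <- rnorm(9, 19.1, 2.76)
    one_way_anova(list(h, p))$p < 0.05
  })
  expect_gt(mean(hits), 0.9)
})

test_that("dip statistic matches exact anchors and the brute-force oracle", {
  # evenly spread samples: the ECDF is linear, dip attains its 1/(2n) floor
  expect_equal(ppgrhythms:::dip_stat_cpp(1:10), 1 / 20, tolerance = 1e-10)
  expect_equal(ppgrhythms:::dip_stat_cpp(seq(0, 1, length.out = 8)), 1 / 16,
               tolerance = 1e-10)
  # two tight clusters of two points approach the distributional limit 1/4
  expect_equal(ppgrhythms:::dip_stat_cpp(c(0, 1e-9, 1, 1 + 1e-9)), 0.25,
               tolerance = 1e-6)
  # affine invariance
  set.seed(44)
  x <- rnorm(60)
  expect_equal(ppgrhythms:::dip_stat_cpp(x),
               ppgrhythms:::dip_stat_cpp(-2.5 * x + 7), tolerance = 1e-10)
  # independent brute-force oracle (grid-restricted, hence an upper bound
  # within one value-grid step) on random tiny samples
  set.seed(9)
  for (i in 1:8) {
    n <- sample(4:5, 1)
    x <- switch(sample(3, 1), runif(n), rnorm(n),
                c(runif(ceiling(n / 2)), 3 + runif(floor(n / 2))))
    fast <- ppgrhythms:::dip_stat_cpp(x)
    oracle <- dip_oracle(x, value_step = 0.01, d_tol = 5e-3)
    expect_gte(oracle + 5e-3 + 1e-9, fast)
    expect_lte(oracle - fast, 0.01 + 5e-3 + 1e-9)
  }
})

test_that("dip test calibration: null level and power", {
  set.seed(77)
  # uniform null: small dip, insignificant
  expect_lt(ppgrhythms:::dip_stat_cpp(runif(500)), 0.03)
  res <- hartigan_dip(runif(300), n_boot = 200, seed = 3)
  expect_lt(res$dip, 0.035)
  expect_gt(res$p, 0.1)
  # type-I error at alpha = 0.05 within [0.03, 0.07] over 1000 null draws
  # (p-values share one simulated null table of the same sample size)
  null_tab <- ppgrhythms:::dip_null_cpp(100L, 2000L)
  dips <- ppgrhythms:::dip_null_cpp(100L, 1000L)
  pvals <- vapply(dips, function(d) mean(null_tab >= d), numeric(1))
  t1 <- mean(pvals < 0.05)
  expect_gte(t1, 0.03); expect_lte(t1, 0.07)
  # power: well-separated two-mode mixture rejects nearly always
  # (replicates share one null table of matching sample size)
  null200 <- ppgrhythms:::dip_null_cpp(200L, 400L)
  rej <- sapply(1:40, function(s) {
    set.seed(500 + s)
    x <- c(rnorm(100, -3, 0.5), rnorm(100, 3, 0.5))
    mean(null200 >= ppgrhythms:::dip_stat_cpp(x)) < 0.01
  })
  expect_gte(mean(rej), 0.95)
  expect_error(hartigan_dip(rep(1, 10)), "identical")
})

test_that("population summary assembles prevalences, stats and tests", {
  set.seed(19)
  n <- 49
  animals <- data.frame(
    animal_id = sprintf("a%02d", 1:n),
    f_heart = runif(n, 0.4, 2.4),
    f_pyloric = runif(n, 0.2, 1.6),
    t_crit_heart = rnorm(n, 25, 1.6),
    t_crit_pyloric = rnorm(n, 19.1, 2.8),
    has_bouts = rep(c(TRUE, FALSE), c(20, 29)),
    is_coherent = rep(c(TRUE, FALSE), c(34, 15))
  )
  sm <- summarize_population(animals,
                             tests = c("freq_correlation", "crit_temp_anova",
                                       "heart_freq_dip"),
                             n_boot = 200, seed = 2)
  expect_equal(unname(sm$prevalence["bouts"]), 20 / 49)
  expect_equal(unname(sm$prevalence["coherent"]), 34 / 49)
  expect_equal(sm$n_animals, n)
  gs <- sm$group_stats
  expect_equal(gs$n[gs$quantity == "t_crit_heart"], n)
  expect_lt(abs(gs$mean[gs$quantity == "t_crit_heart"] - 25), 1)
  expect_true(all(c("freq_correlation", "crit_temp_anova", "heart_freq_dip")
                  %in% names(sm$tests)))
  expect_lt(sm$tests$crit_temp_anova$p, 0.001)
  # empty bout prevalence counts zero
  animals$has_bouts <- FALSE
  sm0 <- summarize_population(animals, tests = character(0))
  expect_equal(unname(sm0$prevalence["bouts"]), 0)
})
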