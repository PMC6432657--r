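#' Pearson correlation with two-sided p-value
#'
#' Sample Pearson r with the classical t transform on n - 2 degrees of
#' freedom (via [stats::cor.test()]).
#'
#' @param x,y Paired numeric vectors, n >= 3, finite, non-constant.
#' @return List with `r`, `p`, `n`.
#' @export
pearson_cor <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("'x' and 'y' must be paired")
  if (length(x) < 3L) stop("need n >= 3")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("inputs must be finite")
  if (stats::var(x) <= 0 || stats::var(y) <= 0) stop("zero-variance input")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' One-way analysis of variance
#'
#' Classical equal-variance one-way ANOVA: the ratio of between-group to
#' within-group mean squares, with the p-value from the F distribution on
#' (k - 1, N - k) degrees of freedom.
#'
#' @param groups List of numeric vectors (>= 2 groups, each with n >= 2).
#' @return List with `F`, `df` (length-2), `p`.
#' @export
one_way_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) stop("need >= 2 groups")
  sizes <- lengths(groups)
  if (any(sizes < 2L)) stop("each group needs n >= 2")
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), sizes))
  ht <- stats::oneway.test(values ~ g, var.equal = TRUE)
  list(F = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

#' Hartigan's dip test of unimodality
#'
#' The dip statistic is the maximum deviation between the empirical CDF and
#' the closest unimodal CDF (computed exactly by bisection over
#' band-constrained convex-then-concave CDFs; see the methods vignette). The
#' p-value is calibrated by Monte Carlo against `n_boot` uniform samples of
#' the same size, the conventional least-favourable unimodal null.
#'
#' @param x Numeric vector, n >= 4, not all values identical.
#' @param n_boot Number of uniform null samples for the p-value.
#' @param seed Integer seed for the bootstrap.
#' @return List with `dip`, `p`, `n`, `n_boot`.
#' @export
hartigan_dip <- function(x, n_boot = 2000, seed = 1L) {
  x <- as.numeric(x)
  if (length(x) < 4L) stop("need n >= 4")
  if (!all(is.finite(x))) stop("inputs must be finite")
  if (length(unique(x)) < 2L) stop("all values identical")
  dip <- dip_stat_cpp(x)
  set.seed(seed)
  null <- dip_null_cpp(length(x), as.integer(n_boot))
  list(dip = dip, p = mean(null >= dip), n = length(x),
       n_boot = as.integer(n_boot))
}

#' Assemble the cross-animal population summary
#'
#' Takes one row of per-animal results (as produced by the per-animal
#' pipeline stages) and computes the population-level quantities: prevalence
#' of inhibitory bouts, prevalence of coherent heart-pyloric datasets, group
#' means and standard deviations of baseline frequencies, Q10s and critical
#' temperatures, plus the configured hypothesis tests.
#'
#' @param animals Data frame with one row per animal; recognized columns
#'   (all optional except `animal_id`): `f_heart`, `f_pyloric`, `q10_heart`,
#'   `q10_pyloric`, `t_crit_heart`, `t_crit_pyloric`, `has_bouts`,
#'   `is_coherent`, `mean_inhib_s`.
#' @param tests Character vector of tests to run, any of
#'   `"freq_correlation"` (heart vs pyloric baseline frequency),
#'   `"crit_temp_anova"` (heart vs pyloric critical temperature),
#'   `"q10_anova"` (heart vs pyloric Q10),
#'   `"heart_freq_dip"` (dip test on baseline heart frequencies).
#' @param n_boot,seed Passed to [hartigan_dip()].
#' @return List of class `population_summary` with elements `animals`,
#'   `n_animals`, `prevalence` (named fractions), `group_stats`
#'   (mean/sd table) and `tests` (named list of test results).
#' @export
summarize_population <- function(animals,
                                 tests = c("freq_correlation",
                                           "crit_temp_anova"),
                                 n_boot = 2000, seed = 1L) {
  animals <- as.data.frame(animals)
  if (nrow(animals) < 1L) stop("need at least one animal")
  has <- function(col) col %in% names(animals) &&
    any(is.finite(animals[[col]]) | animals[[col]] %in% c(TRUE, FALSE))
  prevalence <- c()
  if (has("has_bouts"))
    prevalence["bouts"] <- mean(animals$has_bouts, na.rm = TRUE)
  if (has("is_coherent"))
    prevalence["coherent"] <- mean(animals$is_coherent, na.rm = TRUE)
  num_cols <- intersect(
    c("f_heart", "f_pyloric", "q10_heart", "q10_pyloric",
      "t_crit_heart", "t_crit_pyloric", "mean_inhib_s"),
    names(animals))
  group_stats <- do.call(rbind, lapply(num_cols, function(cl) {
    v <- animals[[cl]][is.finite(animals[[cl]])]
    data.frame(quantity = cl, n = length(v),
               mean = if (length(v)) mean(v) else NA_real_,
               sd = if (length(v) > 1L) stats::sd(v) else NA_real_)
  }))
  results <- list()
  if ("freq_correlation" %in% tests && has("f_heart") && has("f_pyloric")) {
    ok <- is.finite(animals$f_heart) & is.finite(animals$f_pyloric)
    if (sum(ok) >= 3L)
      results$freq_correlation <-
        pearson_cor(animals$f_heart[ok], animals$f_pyloric[ok])
  }
  if ("crit_temp_anova" %in% tests && has("t_crit_heart") &&
      has("t_crit_pyloric")) {
    g1 <- animals$t_crit_heart[is.finite(animals$t_crit_heart)]
    g2 <- animals$t_crit_pyloric[is.finite(animals$t_crit_pyloric)]
    if (length(g1) >= 2L && length(g2) >= 2L)
      results$crit_temp_anova <- one_way_anova(list(heart = g1, pyloric = g2))
  }
  if ("q10_anova" %in% tests && has("q10_heart") && has("q10_pyloric")) {
    g1 <- animals$q10_heart[is.finite(animals$q10_heart)]
    g2 <- animals$q10_pyloric[is.finite(animals$q10_pyloric)]
    if (length(g1) >= 2L && length(g2) >= 2L)
      results$q10_anova <- one_way_anova(list(heart = g1, pyloric = g2))
  }
  if ("heart_freq_dip" %in% tests && has("f_heart")) {
    v <- animals$f_heart[is.finite(animals$f_heart)]
    if (length(v) >= 4L)
      results$heart_freq_dip <- hartigan_dip(v, n_boot = n_boot, seed = seed)
  }
  structure(list(animals = animals, n_animals = nrow(animals),
                 prevalence = prevalence, group_stats = group_stats,
                 tests = results),
            class = "population_summary")
}

#' @export
print.population_summary <- function(x, ...) {
  cat(sprintf("<population_summary> %d animals\n", x$n_animals))
  if (length(x$prevalence))
    cat("  prevalence:",
        paste(sprintf("%s = %.3f", names(x$prevalence), x$prevalence),
              collapse = ", "), "\n")
  if (!is.null(x$group_stats)) {
    for (i in seq_len(nrow(x$group_stats)))
      cat(sprintf("  %s: %.4g +/- %.4g (n = %d)\n",
                  x$group_stats$quantity[i], x$group_stats$mean[i],
                  x$group_stats$sd[i], x$group_stats$n[i]))
  }
  for (nm in names(x$tests)) cat("  test:", nm, "\n")
  invisible(x)
}
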