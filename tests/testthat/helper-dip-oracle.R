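# Brute-force oracle for Hartigan's dip at tiny n: bisection on the radius d
# with feasibility decided by exhaustive search over unimodal CDF values on a
# discrete value grid. Independent of the package's fast band/extrapolation
# feasibility test: this one enumerates candidate value sequences directly
# under the raw constraints (bands from the ECDF jump limits, monotonicity,
# convex prefix / concave suffix sharing the break point).
dip_oracle <- function(x, value_step = 0.002, d_tol = 1e-4) {
  x <- sort(as.numeric(x))
  n <- length(x)
  z <- unique(x)
  cum <- c(0, cumsum(tabulate(match(x, z), length(z))))
  m <- length(z)

  feasible <- function(d) {
    L <- pmax(cum[-1] / n - d, 0)
    U <- pmin(cum[-(m + 1)] / n + d, 1)
    if (any(L > U + 1e-12)) return(FALSE)
    grids <- lapply(seq_len(m), function(j) {
      g <- seq(floor(L[j] / value_step), ceiling(U[j] / value_step)) * value_step
      g[g >= L[j] - 1e-12 & g <= U[j] + 1e-12]
    })
    for (k in seq_len(m)) {
      # DFS over value assignments; prefix convex up to k, concave after,
      # nondecreasing throughout.
      ok <- dfs_assign(1L, numeric(0), grids, z, k, m)
      if (ok) return(TRUE)
    }
    FALSE
  }

  dfs_assign <- function(j, g, grids, z, k, m) {
    if (j > m) return(TRUE)
    for (v in grids[[j]]) {
      if (length(g) >= 1L && v < g[length(g)] - 1e-12) next
      if (length(g) >= 2L) {
        i <- length(g)
        s_prev <- (g[i] - g[i - 1L]) / (z[i] - z[i - 1L])
        s_new <- (v - g[i]) / (z[j] - z[i])
        if (j <= k && s_new < s_prev - 1e-9) next            # convex prefix
        if (j > k && i >= k + 1L && s_new > s_prev + 1e-9) next  # concave suffix
      }
      if (dfs_assign(j + 1L, c(g, v), grids, z, k, m)) return(TRUE)
    }
    FALSE
  }

  lo <- max(diff(cum)) / (2 * n) - value_step
  hi <- 0.5
  while (hi - lo > d_tol) {
    mid <- (lo + hi) / 2
    if (feasible(mid)) hi <- mid else lo <- mid
  }
  hi
}
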