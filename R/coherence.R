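#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computes the first `K` DPSS tapers of length `N` at time-bandwidth product
#' `NW` from the symmetric tridiagonal formulation (eigenvectors of the
#' tridiagonal matrix whose spectrum orders the sequences by in-band energy
#' concentration), then evaluates each taper's actual concentration
#' `lambda_k` as the quadratic form with the sinc kernel. Tapers are
#' orthonormal and ordered by decreasing `lambda`.
#'
#' @param N Samples per window (> K).
#' @param NW Time-bandwidth product (bandwidth W = NW/N in cycles/sample).
#' @param K Number of tapers; must satisfy `K <= 2*NW - 1`.
#' @return List of class `taper_set`: `tapers` (N x K matrix), `lambda`
#'   (concentrations), `N`, `NW`, `K`.
#' @export
dpss_tapers <- function(N, NW = 10, K = 19) {
  if (K > 2 * NW - 1) stop("'K' must satisfy K <= 2*NW - 1")
  if (N <= K) stop("'N' must exceed 'K'")
  W <- NW / N
  i <- seq_len(N) - 1L
  diag_main <- ((N - 1 - 2 * i) / 2)^2 * cos(2 * pi * W)
  diag_off <- (i[-1L] * (N - i[-1L])) / 2
  M <- matrix(0, N, N)
  M[cbind(seq_len(N), seq_len(N))] <- diag_main
  M[cbind(seq_len(N - 1L), 2:N)] <- diag_off
  M[cbind(2:N, seq_len(N - 1L))] <- diag_off
  eg <- eigen(M, symmetric = TRUE)
  V <- eg$vectors[, seq_len(K), drop = FALSE]
  # fix sign convention: each taper starts with a nonnegative mean slope
  for (k in seq_len(K)) {
    s <- sum(V[, k])
    if (abs(s) < 1e-12) s <- V[2L, k] - V[1L, k]
    if (s < 0) V[, k] <- -V[, k]
  }
  # concentrations from the Toeplitz sinc kernel
  d <- outer(i, i, "-")
  S <- sin(2 * pi * W * d) / (pi * d)
  S[cbind(seq_len(N), seq_len(N))] <- 2 * W
  lambda <- colSums(V * (S %*% V))
  ord <- order(lambda, decreasing = TRUE)
  structure(list(tapers = V[, ord, drop = FALSE], lambda = lambda[ord],
                 N = N, NW = NW, K = K),
            class = "taper_set")
}

# Per-session cache: the 1200-point eigendecomposition is the expensive part.
.taper_cache <- new.env(parent = emptyenv())

dpss_cached <- function(N, NW, K) {
  key <- paste(N, NW, K, sep = "_")
  if (is.null(.taper_cache[[key]]))
    .taper_cache[[key]] <- dpss_tapers(N, NW, K)
  .taper_cache[[key]]
}

#' Theoretical multitaper coherence significance threshold
#'
#' The confidence level for magnitude coherence estimated with `2K` degrees
#' of freedom: `C = sqrt(1 - alpha'^(1/(dof/2 - 1)))` with
#' `alpha' = alpha / n_comparisons` (Bonferroni). Peak coherence above `C` is
#' significant at level `alpha` after correcting for `n_comparisons` windows.
#'
#' @param alpha Significance level in (0, 1).
#' @param K Number of tapers (dof = 2K must exceed 2).
#' @param n_comparisons Bonferroni multiplicity (>= 1).
#' @return Threshold coherence magnitude in `[0, 1)`.
#' @export
coherence_threshold <- function(alpha = 0.05, K = 19, n_comparisons = 1) {
  dof <- 2 * K
  if (dof <= 2) stop("need dof = 2K > 2")
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must be in (0, 1)")
  if (n_comparisons < 1) stop("'n_comparisons' must be >= 1")
  a <- alpha / n_comparisons
  sqrt(1 - a^(1 / (dof / 2 - 1)))
}

#' Time-resolved multitaper coherence between two channels
#'
#' For each window of `window_s` seconds advancing by `step_s`, taper-averaged
#' auto- and cross-spectra give the coherency
#' `S_xy / sqrt(S_xx * S_yy)`; its magnitude and phase are stored along with
#' the per-window peak within `band`. Phase is reported in degrees in
#' `[0, 360)`, `y` relative to `x`: delaying `y` by `tau` yields phase
#' `+360 * f * tau` at frequency `f` (positive = `y` lags `x`). Zero-variance
#' windows are flagged (`valid = FALSE`) and skipped.
#'
#' @param x,y [ppg_ts()] objects at equal rates (x = heart, y = pyloric by
#'   convention).
#' @param window_s Window length, s (default 120).
#' @param step_s Window step, s (default 5).
#' @param nw Time-bandwidth product (default 10).
#' @param k Number of tapers (default 19).
#' @param band Peak-search band, Hz.
#' @param n_freq Number of FFT frequencies retained up to Nyquist.
#' @return List of class `ppg_coherence`: `window_times`, `freqs`,
#'   `magnitude` (freq x window matrix), `phase_deg` (same shape), data frame
#'   `peaks` (`time_s`, `peak_coherence`, `peak_freq_hz`, `phase_at_peak_deg`,
#'   `valid`), `dof`.
#' @export
mt_coherence <- function(x, y, window_s = 120, step_s = 5, nw = 10, k = 19,
                         band = c(0.2, 2.5), n_freq = NULL) {
  stopifnot(inherits(x, "ppg_ts"), inherits(y, "ppg_ts"))
  if (abs(x$rate - y$rate) > 1e-9 * x$rate)
    stop("channels must share a sampling rate")
  rate <- x$rate
  n <- min(length(x$samples), length(y$samples))
  nwin <- round(window_s * rate)
  if (n < nwin) stop("input shorter than one coherence window")
  step <- max(1L, round(step_s * rate))
  tp <- dpss_cached(nwin, nw, k)
  nfft <- stats::nextn(nwin, 2)
  nf <- if (is.null(n_freq)) nfft %/% 2L + 1L else n_freq
  freqs <- (seq_len(nf) - 1L) * rate / nfft
  starts <- seq.int(1L, n - nwin + 1L, by = step)
  nwd <- length(starts)
  mag <- ph <- matrix(NA_real_, nf, nwd)
  valid <- logical(nwd)
  pad <- matrix(0, nfft - nwin, k)
  for (j in seq_len(nwd)) {
    xi <- x$samples[starts[j]:(starts[j] + nwin - 1L)]
    yi <- y$samples[starts[j]:(starts[j] + nwin - 1L)]
    if (stats::var(xi) <= .Machine$double.xmin ||
        stats::var(yi) <= .Machine$double.xmin) next
    xi <- xi - mean(xi); yi <- yi - mean(yi)
    X <- stats::mvfft(rbind(tp$tapers * xi, pad))[seq_len(nf), , drop = FALSE]
    Y <- stats::mvfft(rbind(tp$tapers * yi, pad))[seq_len(nf), , drop = FALSE]
    Sxx <- rowMeans(Mod(X)^2)
    Syy <- rowMeans(Mod(Y)^2)
    Sxy <- rowMeans(X * Conj(Y))
    coh <- Sxy / sqrt(pmax(Sxx * Syy, .Machine$double.xmin))
    mag[, j] <- pmin(Mod(coh), 1)
    ph[, j] <- (Arg(coh) * 180 / pi) %% 360
    valid[j] <- TRUE
  }
  centres <- x$t0 + (starts - 1L + (nwin - 1L) / 2) / rate
  sel <- which(freqs >= band[1] & freqs <= band[2])
  if (length(sel) == 0L) stop("'band' contains no frequencies")
  peaks <- data.frame(time_s = centres, peak_coherence = NA_real_,
                      peak_freq_hz = NA_real_, phase_at_peak_deg = NA_real_,
                      valid = valid)
  for (j in which(valid)) {
    i <- sel[which.max(mag[sel, j])]
    peaks$peak_coherence[j] <- mag[i, j]
    peaks$peak_freq_hz[j] <- freqs[i]
    peaks$phase_at_peak_deg[j] <- ph[i, j]
  }
  structure(list(window_times = centres, freqs = freqs, magnitude = mag,
                 phase_deg = ph, peaks = peaks, dof = 2L * k, band = band,
                 rate = rate),
            class = "ppg_coherence")
}

#' @export
print.ppg_coherence <- function(x, ...) {
  cat(sprintf("<ppg_coherence> %d windows, dof %d, band [%g, %g] Hz\n",
              length(x$window_times), x$dof, x$band[1], x$band[2]))
  invisible(x)
}

#' Circular median of angles in degrees
#'
#' The angle (among the observed ones) minimizing the summed circular
#' distance to all others; an ordinary median of raw angles fails at the
#' 0/360 wraparound.
#'
#' @param deg Numeric vector of angles in degrees.
#' @return The circular median, in `[0, 360)`.
#' @export
circular_median_deg <- function(deg) {
  deg <- deg[is.finite(deg)] %% 360
  if (length(deg) == 0L) return(NA_real_)
  costs <- vapply(deg, function(a) {
    d <- abs(deg - a) %% 360
    sum(pmin(d, 360 - d))
  }, numeric(1))
  deg[which.min(costs)]
}

#' Summarize a coherence result against the significance threshold
#'
#' A dataset counts as having coherent heart and pyloric recordings when the
#' per-window peak coherence exceeds the threshold in more than half the
#' windows. The phase summary is the circular median of the phase at peak
#' coherence over the significant windows (over all valid windows if none are
#' significant).
#'
#' @param res A `ppg_coherence` from [mt_coherence()].
#' @param threshold Coherence significance threshold `C`, from
#'   [coherence_threshold()].
#' @return List of class `coherence_summary`: `fraction_significant`,
#'   `is_coherent_dataset`, `median_phase_deg`, `median_peak_coherence`,
#'   `threshold`, `n_windows`.
#' @export
coherence_summary <- function(res, threshold) {
  stopifnot(inherits(res, "ppg_coherence"))
  p <- res$peaks[res$peaks$valid, , drop = FALSE]
  if (nrow(p) == 0L) stop("no valid coherence windows")
  sig <- p$peak_coherence > threshold
  frac <- mean(sig)
  phases <- if (any(sig)) p$phase_at_peak_deg[sig] else p$phase_at_peak_deg
  structure(list(
    fraction_significant = frac,
    is_coherent_dataset = frac > 0.5,
    median_phase_deg = circular_median_deg(phases),
    median_peak_coherence = stats::median(p$peak_coherence),
    threshold = threshold,
    n_windows = nrow(p)
  ), class = "coherence_summary")
}

#' Normalized cross-correlation function
#'
#' Pearson-normalized correlation of two equally sampled channels as a
#' function of lag; with `y = x` this is the autocorrelation, equal to 1 at
#' lag 0. Positive lags mean `y` is shifted later relative to `x`.
#'
#' @param x,y [ppg_ts()] objects at equal rates (`y = x` for autocorrelation).
#' @param max_lag_s Maximum lag magnitude, s.
#' @return Data frame with columns `lag_s` and `corr`.
#' @export
xcorr_fun <- function(x, y = x, max_lag_s = 10) {
  stopifnot(inherits(x, "ppg_ts"), inherits(y, "ppg_ts"))
  if (abs(x$rate - y$rate) > 1e-9 * x$rate)
    stop("channels must share a sampling rate")
  n <- min(length(x$samples), length(y$samples))
  a <- x$samples[seq_len(n)] - mean(x$samples[seq_len(n)])
  b <- y$samples[seq_len(n)] - mean(y$samples[seq_len(n)])
  sa <- sqrt(sum(a^2)); sb <- sqrt(sum(b^2))
  if (sa <= 0 || sb <= 0) stop("zero-variance input")
  L <- as.integer(floor(max_lag_s * x$rate))
  if (L >= n) stop("'max_lag_s' exceeds the record")
  nfft <- stats::nextn(n + L, 2)
  A <- stats::fft(c(a, numeric(nfft - n)))
  B <- stats::fft(c(b, numeric(nfft - n)))
  cc <- Re(stats::fft(Conj(A) * B, inverse = TRUE)) / nfft
  lags <- -L:L
  vals <- cc[ifelse(lags >= 0, lags + 1L, nfft + lags + 1L)] / (sa * sb)
  data.frame(lag_s = lags / x$rate, corr = vals)
}
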