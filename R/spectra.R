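#' Fit an autoregressive model by Burg's method
#'
#' Burg recursion: reflection coefficients are chosen at each stage to
#' minimize the summed forward and backward prediction error. Coefficients are
#' returned in predictor convention, `x_t = sum_k a_k x_{t-k} + e_t`, together
#' with the driving-noise variance. Reflection coefficients from the recursion
#' have modulus < 1, so the fitted model is stable; this is asserted.
#'
#' @param x Numeric vector of windowed samples, length > P.
#' @param P Model order (>= 1).
#' @param demean Subtract the window mean before fitting (default TRUE).
#' @return List of class `ar_model` with elements `order`, `coef`
#'   (length-P numeric), `noise_variance`.
#' @export
burg_fit <- function(x, P, demean = TRUE) {
  x <- as.numeric(x)
  n <- length(x)
  if (!all(is.finite(x))) stop("'x' must be finite")
  if (P < 1L || P >= n) stop("need 1 <= P < length(x)")
  if (demean) x <- x - mean(x)
  E <- sum(x^2) / n
  if (E <= 0) stop("zero-variance input")
  ef <- x
  eb <- x
  a <- numeric(0)
  for (m in seq_len(P)) {
    f <- ef[(m + 1L):n]
    b <- eb[m:(n - 1L)]
    den <- sum(f^2) + sum(b^2)
    if (den <= .Machine$double.xmin) {
      # prediction error exhausted (exactly predictable signal): stop early
      a <- c(a, numeric(P - m + 1L))
      break
    }
    k <- -2 * sum(f * b) / den
    a <- if (m == 1L) k else c(a + k * rev(a), k)
    ef_new <- ef
    ef_new[(m + 1L):n] <- f + k * b
    eb[(m + 1L):n] <- b + k * f
    ef <- ef_new
    E <- E * (1 - k^2)
  }
  # predictor convention: phi = -a for A(z) = 1 + sum a_k z^-k
  phi <- -a
  E <- max(E, .Machine$double.xmin)
  roots_ok <- all(Mod(polyroot(c(1, -phi))) > 1 - 1e-8)
  if (!roots_ok) stop("Burg fit produced an unstable model")
  structure(list(order = P, coef = phi, noise_variance = E),
            class = "ar_model")
}

#' Power spectral density of a fitted AR model
#'
#' Evaluates `power(f) = sigma^2 / rate / |1 - sum_k a_k e^{-2 pi i f k / rate}|^2`
#' on an even grid of `n_freq` points spanning `[0, rate/2]` (two-sided PSD
#' convention: the integral over `[0, Nyquist]` of a white-noise model equals
#' half the process variance).
#'
#' The grid must sample the AR peaks adequately: Burg poles for strong
#' rhythmic components sit very close to the unit circle, so the default grid
#' is dense (8193 points, ~6e-4 Hz spacing at the 10 Hz working rate). An
#' optional evaluation bandwidth floor (`a_k -> a_k rho^k`,
#' `rho = exp(-2 pi bw / rate)`) is available for display smoothing but is
#' off by default.
#'
#' @param model An `ar_model` from [burg_fit()].
#' @param rate Sampling rate in Hz of the data the model was fitted to.
#' @param n_freq Number of frequency grid points (>= 2).
#' @param min_bandwidth_hz Optional bandwidth floor, Hz (0 = raw formula).
#' @return List with `freqs` (Hz) and `power` (amplitude^2 / Hz).
#' @export
ar_psd <- function(model, rate, n_freq = 8193, min_bandwidth_hz = 0) {
  stopifnot(inherits(model, "ar_model"), rate > 0, n_freq >= 2)
  nfft <- 2L * (n_freq - 1L)
  coefs <- c(1, -model$coef)
  if (length(coefs) > nfft)
    stop("'n_freq' too small for the model order")
  if (min_bandwidth_hz > 0) {
    rho <- exp(-2 * pi * min_bandwidth_hz / rate)
    coefs <- coefs * rho^(seq_along(coefs) - 1L)
  }
  A <- stats::fft(c(coefs, numeric(nfft - length(coefs))))[seq_len(n_freq)]
  freqs <- seq(0, rate / 2, length.out = n_freq)
  power <- (model$noise_variance / rate) / (Mod(A)^2)
  list(freqs = freqs, power = power)
}

#' Moving-window Burg spectrogram
#'
#' Splits the conditioned series into windows of `window_s` seconds advancing
#' by `window_s * (1 - overlap)`, fits a Burg AR model of order
#' `floor(window / 4) + 1` samples to each (the classical order choice for the
#' 128-sample window, giving P = 33), and evaluates its PSD on a fixed grid.
#' An incomplete trailing window is dropped, not padded.
#'
#' @param ts Conditioned [ppg_ts()] (typically 10 Hz).
#' @param window_s Window length, s (default 12.8).
#' @param overlap Overlap fraction in `[0, 1)` (default 0.5).
#' @param n_freq Number of frequency grid points on `[0, rate/2]`.
#' @param order AR order; default `floor(nwin / 4) + 1`.
#' @return Object of class `ppg_spectrogram`: `window_times` (window centres,
#'   s), `freqs` (Hz), `power` (matrix `n_freq` x n_windows).
#' @export
spectrogram <- function(ts, window_s = 12.8, overlap = 0.5, n_freq = 8193,
                        order = NULL) {
  stopifnot(inherits(ts, "ppg_ts"), window_s > 0, overlap >= 0, overlap < 1)
  rate <- ts$rate
  nwin <- round(window_s * rate)
  n <- length(ts$samples)
  if (n < nwin) stop("input shorter than one analysis window")
  step <- max(1L, round(nwin * (1 - overlap)))
  if (is.null(order)) order <- nwin %/% 4L + 1L
  starts <- seq.int(1L, n - nwin + 1L, by = step)
  nf <- n_freq
  power <- matrix(NA_real_, nrow = nf, ncol = length(starts))
  freqs <- seq(0, rate / 2, length.out = nf)
  for (j in seq_along(starts)) {
    w <- ts$samples[starts[j]:(starts[j] + nwin - 1L)]
    if (stats::var(w) <= .Machine$double.xmin) {
      power[, j] <- .Machine$double.xmin
      next
    }
    m <- burg_fit(w, order)
    power[, j] <- ar_psd(m, rate, nf)$power
  }
  centres <- ts$t0 + (starts - 1L + (nwin - 1L) / 2) / rate
  structure(list(window_times = centres, freqs = freqs, power = power,
                 rate = rate, window_s = window_s, overlap = overlap),
            class = "ppg_spectrogram")
}

#' @export
print.ppg_spectrogram <- function(x, ...) {
  cat(sprintf("<ppg_spectrogram> %d windows x %d freqs, f in [%g, %g] Hz\n",
              length(x$window_times), length(x$freqs), min(x$freqs),
              max(x$freqs)))
  invisible(x)
}

#' Track the peak-power frequency across spectrogram windows
#'
#' Per window, the frequency of maximum spectral power within `band`; ties are
#' broken toward the lower frequency.
#'
#' @param spec A `ppg_spectrogram`.
#' @param band Length-2 numeric `(lo, hi)` in Hz, within the spectral grid.
#' @return Data frame of class `ppg_freqtrack` with columns `time_s`,
#'   `peak_freq_hz`, `peak_power`; the searched band is kept in
#'   `attr(, "band")`.
#' @export
track_peak <- function(spec, band = c(0.2, 2.5)) {
  stopifnot(inherits(spec, "ppg_spectrogram"), length(band) == 2L,
            band[1] < band[2])
  sel <- which(spec$freqs >= band[1] & spec$freqs <= band[2])
  if (length(sel) == 0L) stop("'band' contains no frequency grid points")
  sub <- spec$power[sel, , drop = FALSE]
  idx <- apply(sub, 2L, which.max)  # first max = lowest frequency on ties
  out <- data.frame(
    time_s = spec$window_times,
    peak_freq_hz = spec$freqs[sel][idx],
    peak_power = sub[cbind(idx, seq_len(ncol(sub)))]
  )
  attr(out, "band") <- band
  class(out) <- c("ppg_freqtrack", "data.frame")
  out
}

#' Baseline frequency as the median of per-window peak frequencies
#'
#' @param track A `ppg_freqtrack` from [track_peak()], or a numeric vector of
#'   peak frequencies.
#' @return Median peak frequency, Hz.
#' @export
baseline_median <- function(track) {
  f <- if (is.data.frame(track)) track$peak_freq_hz else as.numeric(track)
  if (length(f) == 0L) stop("empty frequency track")
  stats::median(f)
}

#' Population-averaged normalized frequency histogram
#'
#' Each animal's frequency collection is binned on a common grid and
#' normalized by its total count (including any mass outside the range), then
#' bar heights are averaged across animals. The resulting bar heights sum to
#' at most 1, with equality when no animal has out-of-range mass.
#'
#' @param freq_list List with one numeric vector of frequencies per animal.
#' @param bin_width Bin width, Hz.
#' @param range Length-2 histogram range in Hz.
#' @return Data frame with columns `bin_lo`, `bin_hi`, `height`.
#' @export
population_histogram <- function(freq_list, bin_width = 0.1,
                                 range = c(0, 2.5)) {
  if (!is.list(freq_list)) freq_list <- list(freq_list)
  if (length(freq_list) == 0L) stop("empty input")
  breaks <- seq(range[1], range[2] + bin_width - 1e-12, by = bin_width)
  nbin <- length(breaks) - 1L
  heights <- vapply(freq_list, function(f) {
    f <- as.numeric(f)
    if (length(f) == 0L) stop("an animal has no frequency values")
    idx <- findInterval(f, breaks, rightmost.closed = TRUE)
    tabulate(idx[idx >= 1L & idx <= nbin], nbin) / length(f)
  }, numeric(length(breaks) - 1L))
  heights <- if (is.null(dim(heights))) heights else rowMeans(heights)
  data.frame(bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1L],
             height = heights)
}
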