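#' Estimate the lag between heart and pyloric channels
#'
#' Finds the integer-sample lag within `+/- max_lag_s` that maximizes the
#' absolute cross-correlation between the channels. Positive lag means the
#' pyloric channel lags the heart. Ties are broken toward the smallest
#' absolute lag. When even the best correlation is negligible the fit is
#' flagged (`significant = FALSE`); downstream subtraction then degenerates
#' gracefully to a near-zero gain.
#'
#' @param heart,pyloric [ppg_ts()] objects at equal rates and equal length.
#' @param max_lag_s Maximum lag magnitude to search, s (less than half the
#'   record).
#' @return List with `lag` (samples), `lag_s` (seconds), `corr` (correlation
#'   at the chosen lag) and `significant` (|corr| >= 0.05).
#' @export
estimate_lag <- function(heart, pyloric, max_lag_s = 3) {
  stopifnot(inherits(heart, "ppg_ts"), inherits(pyloric, "ppg_ts"))
  if (abs(heart$rate - pyloric$rate) > 1e-9 * heart$rate)
    stop("channels must share a sampling rate")
  n <- min(length(heart$samples), length(pyloric$samples))
  if (max_lag_s >= n / heart$rate / 2)
    stop("'max_lag_s' must be less than half the record duration")
  x <- heart$samples[seq_len(n)] - mean(heart$samples[seq_len(n)])
  y <- pyloric$samples[seq_len(n)] - mean(pyloric$samples[seq_len(n)])
  sx <- sqrt(sum(x^2)); sy <- sqrt(sum(y^2))
  if (sx <= 0 || sy <= 0) stop("zero-variance channel")
  L <- as.integer(floor(max_lag_s * heart$rate))
  # FFT cross-correlation: r[k] ~ sum_t x[t] y[t+k] / (sx sy)
  nfft <- stats::nextn(n + L, 2)
  X <- stats::fft(c(x, numeric(nfft - n)))
  Y <- stats::fft(c(y, numeric(nfft - n)))
  cc <- Re(stats::fft(Conj(X) * Y, inverse = TRUE)) / nfft
  lags <- -L:L
  vals <- cc[ifelse(lags >= 0, lags + 1L, nfft + lags + 1L)] / (sx * sy)
  best <- abs(vals) >= max(abs(vals)) - 1e-15
  lag <- lags[best][which.min(abs(lags[best]))]
  corr <- vals[lags == lag]
  list(lag = lag, lag_s = lag / heart$rate, corr = corr,
       significant = abs(corr) >= 0.05)
}

# Shift a vector by `lag` samples (positive = delay), zero-padding the ends.
shift_samples <- function(x, lag) {
  n <- length(x)
  out <- numeric(n)
  if (lag >= 0) {
    if (lag < n) out[(lag + 1L):n] <- x[seq_len(n - lag)]
  } else {
    if (-lag < n) out[seq_len(n + lag)] <- x[(-lag + 1L):n]
  }
  out
}

#' Remove the heart-frequency artifact from the pyloric channel
#'
#' Ordinary least squares of the pyloric signal on the lag-shifted heart
#' signal (plus intercept); the scaled, shifted heart signal is then
#' subtracted. With `fit_window_s` set, the lag/gain fit is refreshed in
#' consecutive windows of that length (useful when frequencies drift during a
#' temperature ramp); the default fits one global lag and gain. A silent heart
#' regressor yields gain 0 and the input returned unchanged.
#'
#' @param heart,pyloric [ppg_ts()] objects at equal rates.
#' @param max_lag_s Lag search range passed to [estimate_lag()].
#' @param fit_window_s `NULL` for one global fit, or a window length in
#'   seconds for per-window refits.
#' @return List with `cleaned` (a [ppg_ts()]) and `fit` (a data frame of class
#'   `subtraction_fit` with one row per fitted window: `start_s`, `lag`,
#'   `gain`, `intercept`, `residual_variance`).
#' @export
regress_subtract <- function(heart, pyloric, max_lag_s = 3,
                             fit_window_s = NULL) {
  stopifnot(inherits(heart, "ppg_ts"), inherits(pyloric, "ppg_ts"))
  if (abs(heart$rate - pyloric$rate) > 1e-9 * heart$rate)
    stop("channels must share a sampling rate")
  n <- min(length(heart$samples), length(pyloric$samples))
  h <- heart$samples[seq_len(n)]
  p <- pyloric$samples[seq_len(n)]
  rate <- heart$rate

  fit_one <- function(hseg, pseg, t_start) {
    if (stats::var(hseg) <= .Machine$double.xmin)
      return(list(cleaned = pseg,
                  row = data.frame(start_s = t_start, lag = 0L, gain = 0,
                                   intercept = 0,
                                   residual_variance = stats::var(pseg))))
    lag_fit <- estimate_lag(ppg_ts(hseg, rate), ppg_ts(pseg, rate),
                            min(max_lag_s, (length(hseg) / rate) / 2 * 0.99))
    hs <- shift_samples(hseg, lag_fit$lag)
    fit <- stats::lsfit(hs, pseg)
    cf <- fit$coefficients
    cleaned <- pseg - (cf[1L] + cf[2L] * hs)
    list(cleaned = cleaned,
         row = data.frame(start_s = t_start, lag = lag_fit$lag,
                          gain = unname(cf[2L]), intercept = unname(cf[1L]),
                          residual_variance = mean(cleaned^2) -
                            mean(cleaned)^2))
  }

  if (is.null(fit_window_s)) {
    res <- fit_one(h, p, heart$t0)
    cleaned <- res$cleaned
    rows <- res$row
  } else {
    wlen <- round(fit_window_s * rate)
    if (wlen < 4L) stop("'fit_window_s' too short")
    starts <- seq.int(1L, n, by = wlen)
    cleaned <- numeric(n)
    rows <- NULL
    for (s in starts) {
      e <- min(s + wlen - 1L, n)
      res <- fit_one(h[s:e], p[s:e], heart$t0 + (s - 1L) / rate)
      cleaned[s:e] <- res$cleaned
      rows <- rbind(rows, res$row)
    }
  }
  class(rows) <- c("subtraction_fit", "data.frame")
  list(cleaned = ppg_ts(cleaned, rate, pyloric$t0, pyloric$label),
       fit = rows)
}
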