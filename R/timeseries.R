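#' Evenly sampled single-channel time series
#'
#' The universal currency of the pipeline: a numeric sample vector with a
#' sampling rate (Hz), a start time (s) and a channel label. Amplitudes are in
#' arbitrary PPG units throughout; no amplitude calibration is assumed.
#'
#' @param samples Numeric vector of finite sample values, length >= 1.
#' @param rate Sampling rate in Hz (> 0).
#' @param t0 Time of the first sample in seconds from recording start.
#' @param label Channel name, e.g. `"heart"`, `"pyloric"`, `"temperature"`.
#' @return An object of class `ppg_ts`.
#' @export
ppg_ts <- function(samples, rate, t0 = 0, label = "signal") {
  samples <- as.numeric(samples)
  if (length(samples) < 1L) stop("'samples' must have length >= 1")
  if (!all(is.finite(samples))) stop("'samples' must be finite")
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0)
    stop("'rate' must be a single positive number (Hz)")
  if (!is.numeric(t0) || length(t0) != 1L || !is.finite(t0))
    stop("'t0' must be a single finite number (s)")
  structure(
    list(samples = samples, rate = rate, t0 = t0, label = as.character(label)[1L]),
    class = "ppg_ts"
  )
}

#' @export
print.ppg_ts <- function(x, ...) {
  cat(sprintf(
    "<ppg_ts> channel '%s': %d samples @ %g Hz, t = [%.6g, %.6g] s\n",
    x$label, length(x$samples), x$rate, x$t0, x$t0 + (length(x$samples) - 1L) / x$rate
  ))
  invisible(x)
}

#' Sample times of a time series
#'
#' @param ts A [ppg_ts()] object.
#' @return Numeric vector of sample times in seconds.
#' @export
ts_times <- function(ts) {
  stopifnot(inherits(ts, "ppg_ts"))
  ts$t0 + (seq_along(ts$samples) - 1L) / ts$rate
}

#' Duration of a time series in seconds
#'
#' @param ts A [ppg_ts()] object.
#' @return Duration spanned by the samples, `n / rate`, in seconds.
#' @export
ts_duration <- function(ts) {
  stopifnot(inherits(ts, "ppg_ts"))
  length(ts$samples) / ts$rate
}

#' Bundle aligned recording channels from one animal
#'
#' Holds the heart channel plus optional pyloric and temperature channels.
#' Channels whose rates differ from the heart channel's by more than 1e-6
#' relative are linearly interpolated onto the heart channel's time grid
#' (the temperature channel is slow, so linear interpolation is adequate).
#'
#' @param heart Heart [ppg_ts()].
#' @param pyloric Optional pyloric [ppg_ts()].
#' @param temperature Optional tank-temperature [ppg_ts()].
#' @param animal_id Identifier carried into population tables.
#' @return An object of class `ppg_recording` with aligned channels.
#' @export
recording_set <- function(heart, pyloric = NULL, temperature = NULL,
                          animal_id = "animal") {
  stopifnot(inherits(heart, "ppg_ts"))
  align <- function(ch) {
    if (is.null(ch)) return(NULL)
    stopifnot(inherits(ch, "ppg_ts"))
    same_rate <- abs(ch$rate - heart$rate) <= 1e-6 * heart$rate
    same_t0 <- abs(ch$t0 - heart$t0) <= 1e-9
    if (same_rate && same_t0) return(ch)
    tt <- ts_times(heart)
    v <- stats::approx(ts_times(ch), ch$samples, xout = tt, rule = 2)$y
    ppg_ts(v, heart$rate, heart$t0, ch$label)
  }
  structure(
    list(heart = heart, pyloric = align(pyloric), temperature = align(temperature),
         animal_id = as.character(animal_id)[1L]),
    class = "ppg_recording"
  )
}

#' @export
print.ppg_recording <- function(x, ...) {
  cat(sprintf("<ppg_recording> animal '%s'\n", x$animal_id))
  for (ch in c("heart", "pyloric", "temperature"))
    if (!is.null(x[[ch]])) {
      cat("  "); print(x[[ch]])
    }
  invisible(x)
}

#' Pipeline run configuration
#'
#' Collects the tunable parameters shared by the analysis stages, with the
#' defaults used throughout: 12.8 s Burg windows at 50% overlap (128 samples at
#' the 10 Hz working rate), a 5 Hz six-order Butterworth low-pass, 120 s
#' multitaper coherence windows stepped by 5 s with time-bandwidth product 10
#' and 19 tapers, and a 0.05 significance level.
#'
#' @param window_s Spectrogram window length in seconds.
#' @param overlap_frac Spectrogram window overlap fraction, in (0, 1).
#' @param lowpass_hz Low-pass cutoff in Hz.
#' @param filter_order Butterworth filter order.
#' @param target_rate_hz Working sampling rate after decimation, Hz.
#' @param coh_window_s Coherence window length, s.
#' @param coh_step_s Coherence window step, s.
#' @param time_bandwidth Multitaper time-bandwidth product NW.
#' @param n_tapers Number of DPSS tapers K (must satisfy K <= 2*NW - 1).
#' @param alpha Significance level.
#' @param n_freq Number of spectral grid points on [0, target Nyquist].
#' @param band Frequency band (Hz) searched for spectral/coherence peaks.
#' @param seed Integer seed recorded with the configuration.
#' @return A list of class `ppg_config`.
#' @export
run_config <- function(window_s = 12.8, overlap_frac = 0.5, lowpass_hz = 5,
                       filter_order = 6, target_rate_hz = 10,
                       coh_window_s = 120, coh_step_s = 5,
                       time_bandwidth = 10, n_tapers = 19, alpha = 0.05,
                       n_freq = 8193, band = c(0.2, 2.5), seed = 1L) {
  stopifnot(window_s > 0, overlap_frac > 0, overlap_frac < 1,
            lowpass_hz > 0, filter_order >= 1, target_rate_hz > 0,
            coh_window_s > 0, coh_step_s > 0, alpha > 0, alpha < 1,
            n_freq >= 2, length(band) == 2L, band[1] < band[2])
  if (n_tapers > 2 * time_bandwidth - 1)
    stop("'n_tapers' must satisfy K <= 2*NW - 1")
  structure(
    list(window_s = window_s, overlap_frac = overlap_frac,
         lowpass_hz = lowpass_hz, filter_order = filter_order,
         target_rate_hz = target_rate_hz, coh_window_s = coh_window_s,
         coh_step_s = coh_step_s, time_bandwidth = time_bandwidth,
         n_tapers = n_tapers, alpha = alpha, n_freq = n_freq, band = band,
         seed = as.integer(seed)),
    class = "ppg_config"
  )
}
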