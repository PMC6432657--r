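#' Remove the voltage offset of a PPG trace
#'
#' Subtracts the sample mean so the returned trace has mean zero.
#'
#' @param ts A [ppg_ts()] of length >= 2.
#' @return A [ppg_ts()] with the same rate, start time and length.
#' @export
remove_offset <- function(ts) {
  stopifnot(inherits(ts, "ppg_ts"), length(ts$samples) >= 2L)
  ppg_ts(ts$samples - mean(ts$samples), ts$rate, ts$t0, ts$label)
}

#' Zero-phase Butterworth low-pass filter
#'
#' Designs a Butterworth low-pass of the given order and applies it forward
#' and backward (`signal::filtfilt`), so the magnitude response is the squared
#' single-pass Butterworth response and the phase response is zero — rhythm
#' timing between channels is preserved.
#'
#' @param ts A [ppg_ts()].
#' @param cutoff Cutoff frequency in Hz (must be below Nyquist).
#' @param order Filter order.
#' @return Filtered [ppg_ts()] of unchanged rate and length.
#' @export
lowpass <- function(ts, cutoff = 5, order = 6) {
  stopifnot(inherits(ts, "ppg_ts"))
  if (cutoff >= ts$rate / 2)
    stop("'cutoff' must be below the Nyquist frequency rate/2")
  bf <- signal::butter(order, cutoff / (ts$rate / 2), type = "low")
  y <- signal::filtfilt(bf, ts$samples)
  ppg_ts(y, ts$rate, ts$t0, ts$label)
}

#' Decimate to a lower sampling rate by integer stride
#'
#' Assumes an anti-aliasing low-pass has already been applied (the default
#' pipeline filters to 5 Hz, exactly the Nyquist of the 10 Hz target). If the
#' attached low-pass record suggests otherwise a warning is emitted, not an
#' error. At the 10 Hz target a 12.8 s analysis window holds exactly 128
#' samples.
#'
#' @param ts A [ppg_ts()].
#' @param target_rate Target rate in Hz; `rate / target_rate` must be an
#'   integer to within 1e-9 relative.
#' @param lowpass_hz Cutoff of the low-pass already applied (Hz), if known;
#'   used only for the anti-aliasing warning.
#' @return Decimated [ppg_ts()].
#' @export
downsample <- function(ts, target_rate = 10, lowpass_hz = NULL) {
  stopifnot(inherits(ts, "ppg_ts"), target_rate > 0)
  stride <- ts$rate / target_rate
  if (abs(stride - round(stride)) > 1e-9 * stride)
    stop("'rate' must be an integer multiple of 'target_rate'")
  stride <- as.integer(round(stride))
  if (!is.null(lowpass_hz) && lowpass_hz > target_rate / 2)
    warning(sprintf(
      "low-pass cutoff %g Hz exceeds the target Nyquist %g Hz; aliasing possible",
      lowpass_hz, target_rate / 2))
  if (stride == 1L) return(ts)
  idx <- seq.int(1L, length(ts$samples), by = stride)
  ppg_ts(ts$samples[idx], target_rate, ts$t0, ts$label)
}

#' Condition a raw PPG trace for spectral analysis
#'
#' The standard conditioning chain: remove the voltage offset, low-pass filter
#' (zero-phase Butterworth, default 5 Hz / order 6), and decimate to the
#' working rate (default 10 Hz, at which the 12.8 s Burg window holds 128
#' samples).
#'
#' @param ts A raw [ppg_ts()] (e.g. 500 Hz).
#' @param config A [run_config()]; its `lowpass_hz`, `filter_order` and
#'   `target_rate_hz` fields are used.
#' @return Conditioned [ppg_ts()] at the working rate.
#' @export
preprocess_ts <- function(ts, config = run_config()) {
  out <- remove_offset(ts)
  out <- lowpass(out, config$lowpass_hz, config$filter_order)
  downsample(out, config$target_rate_hz, lowpass_hz = config$lowpass_hz)
}
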