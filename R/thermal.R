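#' Q10 from log-linear regression of frequency on temperature
#'
#' Pairs each spectrogram window's peak frequency with the window-centre
#' temperature (linear interpolation of the temperature channel), restricts
#' to `fit_range`, and regresses `log10(F)` on `T` by ordinary least squares:
#' `Q10 = 10^(10 * slope)`. The goodness of fit is the squared Pearson
#' correlation of the fitted pairs. A constant frequency yields slope 0,
#' Q10 = 1 and an undefined R2 reported as 0 with a warning. Only the rising
#' ramp below the critical temperature should be included in `fit_range`.
#'
#' @param track A `ppg_freqtrack` from [track_peak()].
#' @param temp Temperature [ppg_ts()] aligned with the recording.
#' @param fit_range Length-2 temperature range (deg C) to fit.
#' @return List of class `ramp_fit`: `q10`, `slope` (log10(Hz)/degC),
#'   `intercept`, `r_squared`, `n_points`, `fit_range`.
#' @export
q10_fit <- function(track, temp, fit_range) {
  stopifnot(is.data.frame(track), inherits(temp, "ppg_ts"),
            length(fit_range) == 2L, fit_range[1] < fit_range[2])
  Tw <- stats::approx(ts_times(temp), temp$samples, xout = track$time_s,
                      rule = 2)$y
  keep <- Tw >= fit_range[1] & Tw <= fit_range[2]
  f <- track$peak_freq_hz[keep]
  Tk <- Tw[keep]
  if (length(f) < 5L) stop("fewer than 5 (temperature, frequency) pairs in range")
  if (any(f <= 0)) stop("non-positive frequency inside the fit range")
  y <- log10(f)
  if (stats::var(y) <= .Machine$double.xmin) {
    warning("frequency constant over the fit range; R2 undefined, reported as 0")
    return(structure(list(q10 = 1, slope = 0, intercept = mean(y),
                          r_squared = 0, n_points = length(f),
                          fit_range = fit_range),
                     class = "ramp_fit"))
  }
  fit <- stats::lsfit(Tk, y)
  m <- unname(fit$coefficients[2L])
  structure(list(
    q10 = 10^(10 * m),
    slope = m,
    intercept = unname(fit$coefficients[1L]),
    r_squared = stats::cor(Tk, y)^2,
    n_points = length(f),
    fit_range = fit_range
  ), class = "ramp_fit")
}

#' @export
print.ramp_fit <- function(x, ...) {
  cat(sprintf("<ramp_fit> Q10 = %.4f (slope %.5f /degC, R2 = %.3f, n = %d, fit %g-%g degC)\n",
              x$q10, x$slope, x$r_squared, x$n_points,
              x$fit_range[1], x$fit_range[2]))
  invisible(x)
}

#' Detect the critical ("crash") temperature on a rising ramp
#'
#' Operationalizes "the rhythm became irregular and the frequency decreased":
#' scanning windows along the rising-temperature segment, the critical
#' temperature is the temperature of the first window of the first run of at
#' least `persist_windows` consecutive windows in which both
#' \itemize{
#'   \item the tracked peak frequency falls below `freq_drop_frac` (default
#'     90%) of its running maximum over the ramp so far, and
#'   \item the irregularity index — the fraction of in-band spectral power
#'     concentrated within `peak_halfwidth_hz` of the tracked peak — falls
#'     below `peakiness_frac` (default 50%) of its baseline median (baseline =
#'     windows within `baseline_band_degC` of the coolest observed
#'     temperature).
#' }
#' If the two criteria never co-occur the result is `NA` (undetermined),
#' matching ramps whose irregularities preclude a determination.
#'
#' @param track A `ppg_freqtrack` from [track_peak()] (band attribute used).
#' @param temp Temperature [ppg_ts()].
#' @param spec The `ppg_spectrogram` the track came from.
#' @param freq_drop_frac Fraction of the running maximum frequency below which
#'   criterion (a) fires.
#' @param peakiness_frac Fraction of the baseline median irregularity index
#'   below which criterion (b) fires.
#' @param persist_windows Number of consecutive windows both criteria must
#'   hold.
#' @param peak_halfwidth_hz Half-width (Hz) of the integration band around the
#'   tracked peak used by the irregularity index.
#' @param baseline_band_degC Temperature band above the minimum defining the
#'   baseline windows.
#' @return List of class `crash_detection`: `critical_temp` (deg C or `NA`),
#'   `critical_time_s`, `peakiness_baseline`, and the per-window diagnostics
#'   data frame `windows`.
#' @export
detect_critical_temperature <- function(track, temp, spec,
                                        freq_drop_frac = 0.9,
                                        peakiness_frac = 0.5,
                                        persist_windows = 3L,
                                        peak_halfwidth_hz = 0.1,
                                        baseline_band_degC = 1.0) {
  stopifnot(is.data.frame(track), inherits(temp, "ppg_ts"),
            inherits(spec, "ppg_spectrogram"))
  band <- attr(track, "band")
  if (is.null(band)) band <- c(min(spec$freqs), max(spec$freqs))
  Tw <- stats::approx(ts_times(temp), temp$samples, xout = track$time_s,
                      rule = 2)$y
  # rising segment: from the start to the hottest window
  i_max <- which.max(Tw)
  rising <- seq_len(i_max)
  if (length(rising) < persist_windows + 1L || Tw[i_max] <= Tw[1L] + 1e-9)
    stop("no rising temperature segment")
  sel <- which(spec$freqs >= band[1] & spec$freqs <= band[2])
  bandpow <- colSums(spec$power[sel, , drop = FALSE])
  fsel <- spec$freqs[sel]
  localpow <- vapply(seq_along(track$time_s), function(j) {
    near <- abs(fsel - track$peak_freq_hz[j]) <= peak_halfwidth_hz
    sum(spec$power[sel[near], j])
  }, numeric(1))
  peakiness <- localpow / pmax(bandpow, .Machine$double.xmin)
  base_idx <- rising[Tw[rising] <= min(Tw[rising]) + baseline_band_degC]
  base_peakiness <- stats::median(peakiness[base_idx])
  f <- track$peak_freq_hz[rising]
  runmax <- cummax(f)
  crit_a <- f < freq_drop_frac * runmax
  crit_b <- peakiness[rising] < peakiness_frac * base_peakiness
  both <- crit_a & crit_b
  hit <- NA_integer_
  r <- rle(both)
  ends <- cumsum(r$lengths)
  ok <- which(r$values & r$lengths >= persist_windows)
  if (length(ok) > 0L) hit <- ends[ok[1L]] - r$lengths[ok[1L]] + 1L
  windows <- data.frame(time_s = track$time_s[rising], temp_C = Tw[rising],
                        peak_freq_hz = f, peakiness = peakiness[rising],
                        freq_criterion = crit_a, irregularity_criterion = crit_b)
  structure(list(
    critical_temp = if (is.na(hit)) NA_real_ else Tw[rising][hit],
    critical_time_s = if (is.na(hit)) NA_real_ else track$time_s[rising][hit],
    peakiness_baseline = base_peakiness,
    windows = windows
  ), class = "crash_detection")
}

#' Full per-channel temperature-ramp analysis
#'
#' Conditions the channel, computes the Burg spectrogram and peak track,
#' detects the critical temperature, and fits Q10 on the rising ramp below it
#' (full rising ramp, with a message, when the crash is undetermined).
#'
#' @param ts Raw channel [ppg_ts()].
#' @param temp Temperature [ppg_ts()].
#' @param config A [run_config()].
#' @param fit_range Optional explicit temperature fit range; default from the
#'   coolest window temperature up to the detected critical temperature.
#' @return List of class `ramp_analysis`: `fit` (a `ramp_fit`), `crash`
#'   (a `crash_detection`), `track`, `spectrogram`.
#' @export
analyze_ramp <- function(ts, temp, config = run_config(), fit_range = NULL) {
  cond <- preprocess_ts(ts, config)
  spec <- spectrogram(cond, config$window_s, config$overlap_frac,
                      config$n_freq)
  track <- track_peak(spec, config$band)
  crash <- detect_critical_temperature(track, temp, spec)
  if (is.null(fit_range)) {
    Tw <- stats::approx(ts_times(temp), temp$samples, xout = track$time_s,
                        rule = 2)$y
    hi <- if (is.na(crash$critical_temp)) {
      message("critical temperature undetermined; fitting the full rising ramp")
      max(Tw)
    } else crash$critical_temp
    fit_range <- c(min(Tw), hi)
  }
  fit <- q10_fit(track, temp, fit_range)
  structure(list(fit = fit, crash = crash, track = track,
                 spectrogram = spec),
            class = "ramp_analysis")
}
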