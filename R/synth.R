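#' Parameters for the synthetic two-channel PPG generator
#'
#' Defaults emulate the study conditions the analysis targets: a pulsatile
#' heart rhythm (raised-cosine pulse train, 0.6 Hz baseline), a smooth
#' asymmetric pyloric oscillation (0.8 Hz baseline), a heart-frequency
#' artifact mixed into the pyloric channel at a fixed phase offset of the
#' heart cycle (190 degrees), two-state Markov bradycardia bouts with
#' exponential dwell times (means 300 s active / 30 s inhibitory) that
#' suppress heart amplitude and slow the pyloric frequency, and
#' Q10-governed temperature scaling (heart 2.007, pyloric 2.040) with a
#' programmed irregular "crash" above a critical temperature (heart 25.0 C,
#' pyloric 19.1 C).
#'
#' @param f_heart,f_pyloric Baseline frequencies, Hz.
#' @param heart_pulse_width Full width of the raised-cosine heart pulse, s;
#'   `NULL` (default) uses 0.8 of the baseline heart period, matching the
#'   smooth, nearly sinusoidal pulses of low-pass-filtered PPG traces.
#' @param amp_heart,amp_pyloric Channel amplitudes (arbitrary PPG units).
#' @param coupling Fraction of the heart waveform mixed into the pyloric
#'   channel, in `[0, 1]`.
#' @param coupling_phase_deg Delay of the mixed-in heart waveform, in degrees
#'   of the heart cycle; positive means the pyloric copy lags the heart.
#' @param noise_sd White-noise standard deviation added to each channel.
#' @param freq_jitter_rel Relative sd of the slow frequency wander
#'   (Ornstein-Uhlenbeck process multiplying each channel's instantaneous
#'   frequency); rhythms in vivo are quasi-periodic, not clocklike, and this
#'   wander is what gives the spectrogram its finite-width bands. Set to 0
#'   for strictly periodic channels.
#' @param freq_jitter_tau_s Correlation time of the frequency wander, s.
#' @param bouts Logical: simulate the two-state Markov bout process.
#' @param bout_mean_active_s,bout_mean_inhib_s Mean exponential dwell times, s.
#' @param bout_freq_factor Multiplier on the pyloric frequency during an
#'   inhibitory bout.
#' @param bout_amp_factor Multiplier on the heart amplitude during an
#'   inhibitory bout.
#' @param post_bout_overshoot Logical: transient heart-amplitude overshoot
#'   after each bout (off by default).
#' @param q10_heart,q10_pyloric Temperature coefficients (> 0).
#' @param t_crit_heart,t_crit_pyloric Critical (crash) temperatures, deg C.
#' @param crash_jitter_rel Post-crash cycle-period jitter, as a fraction of
#'   the instantaneous period (Gaussian sd).
#' @param crash_jitter_sd Absolute jitter sd in seconds; overrides
#'   `crash_jitter_rel` when non-`NULL`.
#' @param crash_decay_tau_s Time constant of the post-crash decay of frequency
#'   (toward baseline) and amplitude, s.
#' @param crash_amp_floor Fraction of the pre-crash amplitude retained after
#'   the crash decay.
#' @param ref_temp Reference temperature for the Q10 law, deg C.
#' @param duration_s Recording length, s.
#' @param rate Sampling rate, Hz.
#' @param seed Integer seed; the same seed reproduces the recording bitwise.
#' @return A list of class `synth_params`.
#' @export
synth_params <- function(f_heart = 0.6, f_pyloric = 0.8,
                         heart_pulse_width = NULL,
                         amp_heart = 1, amp_pyloric = 0.6,
                         coupling = 0.3, coupling_phase_deg = 190,
                         noise_sd = 0.02,
                         freq_jitter_rel = 0.01, freq_jitter_tau_s = 5,
                         bouts = FALSE,
                         bout_mean_active_s = 300, bout_mean_inhib_s = 30,
                         bout_freq_factor = 0.6, bout_amp_factor = 0.1,
                         post_bout_overshoot = FALSE,
                         q10_heart = 2.007, q10_pyloric = 2.040,
                         t_crit_heart = 25.0, t_crit_pyloric = 19.1,
                         crash_jitter_rel = 0.3, crash_jitter_sd = NULL,
                         crash_decay_tau_s = 60, crash_amp_floor = 0.2,
                         ref_temp = 11, duration_s = 1800, rate = 500,
                         seed = 1L) {
  p <- as.list(environment())
  if (p$rate <= 0) stop("'rate' must be positive")
  if (is.null(p$heart_pulse_width)) p$heart_pulse_width <- 0.8 / p$f_heart
  nyq <- p$rate / 2
  if (p$f_heart <= 0 || p$f_heart >= nyq)
    stop("'f_heart' must lie in (0, rate/2)")
  if (p$f_pyloric <= 0 || p$f_pyloric >= nyq)
    stop("'f_pyloric' must lie in (0, rate/2)")
  if (p$coupling < 0 || p$coupling > 1) stop("'coupling' must be in [0, 1]")
  if (p$bout_mean_active_s <= 0 || p$bout_mean_inhib_s <= 0)
    stop("bout dwell means must be > 0")
  if (p$q10_heart <= 0 || p$q10_pyloric <= 0) stop("Q10 values must be > 0")
  if (p$noise_sd < 0) stop("'noise_sd' must be >= 0")
  if (p$freq_jitter_rel < 0 || p$freq_jitter_tau_s <= 0)
    stop("frequency-wander parameters must be nonnegative (tau > 0)")
  if (p$heart_pulse_width <= 0 || p$heart_pulse_width >= 1 / p$f_heart)
    stop("'heart_pulse_width' must be positive and shorter than one heart period")
  if (p$duration_s <= 0) stop("'duration_s' must be positive")
  class(p) <- "synth_params"
  p
}

# Raised-cosine pulse evaluated at cycle phase (in cycles); pulse centred at
# phase 0.5 with half-width hw (cycles).
raised_cosine_pulse <- function(phase_cycles, hw) {
  u <- phase_cycles - floor(phase_cycles)
  y <- numeric(length(u))
  inside <- abs(u - 0.5) < hw
  y[inside] <- 0.5 * (1 + cos(pi * (u[inside] - 0.5) / hw))
  y
}

# Asymmetric smooth oscillation (two harmonics) for the pyloric waveform.
pyloric_wave <- function(phase_cycles) {
  0.8 * sin(2 * pi * phase_cycles) + 0.1 * sin(4 * pi * phase_cycles + 0.8)
}

# Alternating exponential-dwell state path; returns a data frame of segments
# (state, start_s, end_s) covering [0, duration_s].
simulate_bout_segments <- function(mean_active_s, mean_inhib_s, duration_s) {
  state <- 1L  # start active
  t <- 0
  starts <- ends <- numeric(0)
  states <- integer(0)
  while (t < duration_s) {
    dwell <- stats::rexp(1, 1 / if (state == 1L) mean_active_s else mean_inhib_s)
    starts <- c(starts, t)
    ends <- c(ends, min(t + dwell, duration_s))
    states <- c(states, state)
    t <- t + dwell
    state <- 1L - state
  }
  data.frame(state = states, start_s = starts, end_s = ends)
}

# Slow multiplicative frequency wander: stationary Ornstein-Uhlenbeck process
# with sd `rel` and correlation time `tau_s`, simulated on a coarse 0.5 s grid
# and linearly interpolated to the sampling grid.
freq_wander <- function(n, rate, rel, tau_s) {
  if (rel <= 0) return(numeric(n))
  dur <- (n - 1L) / rate
  tc <- seq(0, dur + 0.5, by = 0.5)
  ph <- exp(-0.5 / tau_s)
  z <- stats::rnorm(length(tc), 0, rel * sqrt(1 - ph^2))
  w <- numeric(length(tc))
  w[1L] <- stats::rnorm(1, 0, rel)
  for (i in 2:length(tc)) w[i] <- w[i - 1L] * ph + z[i]
  stats::approx(tc, w, xout = (seq_len(n) - 1L) / rate)$y
}

# Per-sample 0/1 state vector from explicit intervals of the inhibitory state.
state_from_intervals <- function(n, rate, t0, intervals) {
  st <- rep(1L, n)
  if (is.null(intervals) || NROW(intervals) == 0L) return(st)
  tt <- t0 + (seq_len(n) - 1L) / rate
  for (i in seq_len(NROW(intervals)))
    st[tt >= intervals[i, 1] & tt < intervals[i, 2]] <- 0L
  st
}

#' Generate a baseline (constant-temperature) synthetic recording
#'
#' Builds the heart channel as a raised-cosine pulse train plus white noise
#' and the pyloric channel as a smooth two-harmonic oscillation plus a
#' delayed, scaled copy of the heart waveform (the artifact the subtraction
#' stage removes) plus noise. The bout process, when enabled, multiplies the
#' heart amplitude by `bout_amp_factor` and the pyloric frequency by
#' `bout_freq_factor` while in the inhibitory state.
#'
#' @param params A [synth_params()] object.
#' @param bout_intervals Optional two-column matrix/data frame of explicit
#'   inhibitory intervals `(start_s, end_s)`; overrides the Markov process.
#' @param channels Character vector choosing which channels to synthesize
#'   (subset of `c("heart", "pyloric")`).
#' @return A list of class `synth_recording` with elements `recording`
#'   (a [recording_set()]) and `truth` (per-sample state sequence, bout
#'   segment table, instantaneous frequencies and the injected parameters).
#' @export
gen_baseline <- function(params, bout_intervals = NULL,
                         channels = c("heart", "pyloric")) {
  stopifnot(inherits(params, "synth_params"))
  channels <- match.arg(channels, c("heart", "pyloric"), several.ok = TRUE)
  set.seed(params$seed)
  rate <- params$rate
  n <- round(params$duration_s * rate)
  dt <- 1 / rate

  if (!is.null(bout_intervals)) {
    bi <- as.matrix(bout_intervals)
    state <- state_from_intervals(n, rate, 0, bi)
    seg <- data.frame(state = 0L, start_s = bi[, 1], end_s = bi[, 2])
  } else if (isTRUE(params$bouts)) {
    seg <- simulate_bout_segments(params$bout_mean_active_s,
                                  params$bout_mean_inhib_s, params$duration_s)
    inhib <- seg[seg$state == 0L, c("start_s", "end_s"), drop = FALSE]
    state <- state_from_intervals(n, rate, 0, as.matrix(inhib))
  } else {
    seg <- data.frame(state = 1L, start_s = 0, end_s = params$duration_s)
    state <- rep(1L, n)
  }

  hw <- params$heart_pulse_width * params$f_heart / 2  # half width, cycles
  wander_h <- freq_wander(n, rate, params$freq_jitter_rel,
                          params$freq_jitter_tau_s)
  f_heart_inst <- params$f_heart * (1 + wander_h)
  phase_h <- cumsum(f_heart_inst) * dt
  env_h <- ifelse(state == 1L, 1, params$bout_amp_factor)
  if (isTRUE(params$post_bout_overshoot) && any(state == 0L)) {
    tt <- (seq_len(n) - 1L) * dt
    ends <- seg$end_s[seg$state == 0L]
    for (te in ends) {
      w <- tt >= te & tt < te + 30
      env_h[w] <- env_h[w] * (1 + 0.5 * exp(-(tt[w] - te) / 10))
    }
  }

  heart <- pyl <- NULL
  if ("heart" %in% channels) {
    y <- params$amp_heart * env_h * raised_cosine_pulse(phase_h, hw)
    if (params$noise_sd > 0) y <- y + stats::rnorm(n, 0, params$noise_sd)
    heart <- ppg_ts(y, rate, 0, "heart")
  }
  wander_p <- freq_wander(n, rate, params$freq_jitter_rel,
                          params$freq_jitter_tau_s)
  f_pyl_inst <- params$f_pyloric * (1 + wander_p) *
    ifelse(state == 1L, 1, params$bout_freq_factor)
  if ("pyloric" %in% channels) {
    phase_p <- cumsum(f_pyl_inst) * dt
    y <- params$amp_pyloric * pyloric_wave(phase_p)
    if (params$coupling > 0) {
      delayed <- raised_cosine_pulse(
        phase_h - params$coupling_phase_deg / 360, hw)
      y <- y + params$coupling * params$amp_heart * env_h * delayed
    }
    if (params$noise_sd > 0) y <- y + stats::rnorm(n, 0, params$noise_sd)
    pyl <- ppg_ts(y, rate, 0, "pyloric")
  }

  if (is.null(heart))
    stop("the heart channel is required; include \"heart\" in 'channels'")
  truth <- list(
    state_sequence = state,
    bout_segments = seg,
    f_heart = params$f_heart,
    f_heart_inst = f_heart_inst,
    f_pyloric_inst = if ("pyloric" %in% channels) f_pyl_inst else NULL,
    true_phase_offset_deg = params$coupling_phase_deg,
    params = params
  )
  structure(list(recording = recording_set(heart, pyl, NULL, "synthetic"),
                 truth = truth),
            class = "synth_recording")
}

# Post-crash instantaneous frequency: jittered cycles whose nominal frequency
# decays from the value at the crash toward baseline.
crash_freq_profile <- function(t_rel, f_at_crash, f_base, tau, jitter_rel,
                               jitter_sd, dt) {
  n <- length(t_rel)
  f_inst <- numeric(n)
  i <- 1L
  while (i <= n) {
    f_target <- f_base + (f_at_crash - f_base) * exp(-t_rel[i] / tau)
    period_nom <- 1 / f_target
    sd <- if (is.null(jitter_sd)) jitter_rel * period_nom else jitter_sd
    period <- period_nom + stats::rnorm(1, 0, sd)
    period <- max(period, 0.2 * period_nom)
    len <- max(1L, round(period / dt))
    j <- min(n, i + len - 1L)
    f_inst[i:j] <- 1 / period
    i <- j + 1L
  }
  f_inst
}

#' Generate a temperature-ramp synthetic recording
#'
#' The tank temperature rises linearly from `T_start` to `T_end` over
#' `ramp_duration_s` starting at `t_start_s`. Below its critical temperature
#' each channel's instantaneous frequency follows
#' `f(T) = f_base * Q10^((T - ref_temp) / 10)`; once the temperature crosses
#' the channel's critical temperature the rhythm "crashes": cycle periods
#' acquire Gaussian jitter, the mean frequency decays back toward baseline and
#' the amplitude decays toward `crash_amp_floor` of its pre-crash value.
#'
#' @param params A [synth_params()] object.
#' @param ramp List or numeric vector `(t_start_s, T_start, T_end,
#'   ramp_duration_s)`.
#' @param channels Channels to synthesize, subset of `c("heart", "pyloric")`.
#' @return A list of class `synth_recording`; the recording includes a
#'   `temperature` channel, and `truth` carries the injected Q10s and critical
#'   temperatures.
#' @export
gen_ramp <- function(params, ramp, channels = c("heart", "pyloric")) {
  stopifnot(inherits(params, "synth_params"))
  channels <- match.arg(channels, c("heart", "pyloric"), several.ok = TRUE)
  r <- as.numeric(unlist(ramp))
  if (length(r) != 4L)
    stop("'ramp' must supply (t_start_s, T_start, T_end, ramp_duration_s)")
  t_start <- r[1]; T_start <- r[2]; T_end <- r[3]; ramp_dur <- r[4]
  if (T_end <= T_start) stop("heating ramp requires T_start < T_end")
  if (t_start < 0 || ramp_dur <= 0 || t_start + ramp_dur > params$duration_s)
    stop("ramp window exceeds the recording duration")
  set.seed(params$seed)
  rate <- params$rate
  n <- round(params$duration_s * rate)
  dt <- 1 / rate
  tt <- (seq_len(n) - 1L) * dt
  temp <- T_start + (T_end - T_start) *
    pmin(pmax((tt - t_start) / ramp_dur, 0), 1)

  make_channel <- function(f_base, q10, t_crit, wavefun, amp, label) {
    wander <- freq_wander(n, rate, params$freq_jitter_rel,
                          params$freq_jitter_tau_s)
    f_nom <- f_base * q10^((temp - params$ref_temp) / 10) * (1 + wander)
    crash_idx <- which(temp >= t_crit)[1L]
    env <- rep(1, n)
    f_inst <- f_nom
    if (!is.na(crash_idx)) {
      post <- crash_idx:n
      t_rel <- tt[post] - tt[crash_idx]
      f_inst[post] <- crash_freq_profile(
        t_rel, f_nom[crash_idx], f_base, params$crash_decay_tau_s,
        params$crash_jitter_rel, params$crash_jitter_sd, dt)
      env[post] <- params$crash_amp_floor + (1 - params$crash_amp_floor) *
        exp(-t_rel / params$crash_decay_tau_s)
    }
    phase <- cumsum(f_inst) * dt
    y <- amp * env * wavefun(phase)
    if (params$noise_sd > 0) y <- y + stats::rnorm(n, 0, params$noise_sd)
    list(ts = ppg_ts(y, rate, 0, label), f_inst = f_inst,
         crash_time_s = if (is.na(crash_idx)) NA_real_ else tt[crash_idx])
  }

  hw <- params$heart_pulse_width * params$f_heart / 2
  heart <- make_channel(params$f_heart, params$q10_heart, params$t_crit_heart,
                        function(p) raised_cosine_pulse(p, hw),
                        params$amp_heart, "heart")
  pyl <- if ("pyloric" %in% channels)
    make_channel(params$f_pyloric, params$q10_pyloric, params$t_crit_pyloric,
                 pyloric_wave, params$amp_pyloric, "pyloric") else NULL

  temp_ts <- ppg_ts(temp, rate, 0, "temperature")
  truth <- list(
    true_q10 = c(heart = params$q10_heart, pyloric = params$q10_pyloric),
    true_t_crit = c(heart = params$t_crit_heart, pyloric = params$t_crit_pyloric),
    f_heart_inst = heart$f_inst,
    f_pyloric_inst = if (!is.null(pyl)) pyl$f_inst else NULL,
    crash_time_s = c(heart = heart$crash_time_s,
                     pyloric = if (!is.null(pyl)) pyl$crash_time_s else NA_real_),
    params = params, ramp = r
  )
  structure(list(recording = recording_set(heart$ts,
                                           if (!is.null(pyl)) pyl$ts else NULL,
                                           temp_ts, "synthetic_ramp"),
                 truth = truth),
            class = "synth_recording")
}

#' Draw paired baseline frequencies for a synthetic population
#'
#' Samples (heart, pyloric) baseline frequency pairs from a bivariate Gaussian
#' copula with uniform marginals on the stated ranges. The latent normal
#' correlation is chosen as `2 * sin(pi * corr / 6)` so that the Pearson
#' correlation of the uniform marginals equals the requested `corr`.
#'
#' @param n_animals Number of animals (>= 3).
#' @param corr Target Pearson correlation, in (-1, 1).
#' @param heart_range,pyloric_range Frequency ranges (Hz) of the uniform
#'   marginals.
#' @param seed Integer seed.
#' @return Data frame with columns `animal_id`, `f_heart`, `f_pyloric`.
#' @export
gen_population <- function(n_animals, corr, heart_range = c(0.4, 2.4),
                           pyloric_range = c(0.2, 1.6), seed = 1L) {
  if (n_animals < 3) stop("'n_animals' must be >= 3")
  if (corr <= -1 || corr >= 1) stop("'corr' must be in (-1, 1)")
  if (heart_range[1] >= heart_range[2] || pyloric_range[1] >= pyloric_range[2])
    stop("frequency ranges must be increasing")
  set.seed(seed)
  rho_z <- 2 * sin(pi * corr / 6)
  z1 <- stats::rnorm(n_animals)
  z2 <- rho_z * z1 + sqrt(1 - rho_z^2) * stats::rnorm(n_animals)
  u1 <- stats::pnorm(z1); u2 <- stats::pnorm(z2)
  data.frame(
    animal_id = sprintf("animal%02d", seq_len(n_animals)),
    f_heart = heart_range[1] + diff(heart_range) * u1,
    f_pyloric = pyloric_range[1] + diff(pyloric_range) * u2
  )
}
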