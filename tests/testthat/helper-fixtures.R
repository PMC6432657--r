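# Shared fixtures, built once per session and cached.
.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- builder()
  .fixture_cache[[name]]
}

sine_ts <- function(freq, rate = 500, dur = 60, amp = 1, phase = 0) {
  t <- (seq_len(round(dur * rate)) - 1) / rate
  ppg_ts(amp * sin(2 * pi * freq * t + phase), rate, 0, "sine")
}

# Conditioned 300 s heart recording at 1.1 Hz with default (quasi-periodic)
# generator settings, plus its spectrogram and track.
fix_baseline_11 <- function() fixture("baseline11", function() {
  cfg <- run_config()
  sim <- gen_baseline(synth_params(f_heart = 1.1, duration_s = 300, seed = 7),
                      channels = "heart")
  cond <- preprocess_ts(sim$recording$heart, cfg)
  spec <- spectrogram(cond)
  list(sim = sim, cond = cond, spec = spec, track = track_peak(spec))
})

# Coupled two-channel baseline recording (coherent pair, phase 190 deg).
fix_coupled <- function() fixture("coupled", function() {
  cfg <- run_config()
  sim <- gen_baseline(synth_params(f_heart = 1.1, f_pyloric = 0.5,
                                   coupling = 0.5, coupling_phase_deg = 190,
                                   duration_s = 600, seed = 5))
  list(sim = sim,
       heart = preprocess_ts(sim$recording$heart, cfg),
       pyloric = preprocess_ts(sim$recording$pyloric, cfg))
})
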