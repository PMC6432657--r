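# ppgrhythms

Analysis of simultaneous *in vivo* photoplethysmogram (PPG) recordings of
the crustacean heart and pyloric (stomach) rhythms. Sensors on the carapace
record both motor rhythms as 500 Hz voltage traces; the two rhythms occupy
overlapping frequency bands (heart ~0.3–2.3 Hz, pyloric ~0.2–1.6 Hz), the
heart bleeds into the pyloric sensor as a phase-shifted artifact, the heart
shows intermittent inhibitory bouts (bradycardia), and both rhythms speed up
with temperature until they crash. This package implements the full analysis
chain for such data, plus a synthetic generator with ground truth so every
stage can be verified without animal recordings.

## What it computes

* **Conditioning** — offset removal, zero-phase six-order Butterworth
  low-pass at 5 Hz, decimation to 10 Hz (so a 12.8 s window holds 128
  samples).
* **Frequency tracking** — moving-window Burg autoregressive spectrograms
  (order `P = window/4 + 1 = 33`, 50% overlap); per-window rhythm frequency
  is the in-band peak of `P(f) = σ²/r / |1 − Σₖ aₖ e^{−2πifk/r}|²`; baseline
  frequency is the median across windows; population histograms are
  per-animal normalized then averaged.
* **Heart-artifact subtraction** — cross-correlation lag estimate plus
  ordinary least squares of the pyloric signal on the shifted heart signal;
  the scaled copy is subtracted before pyloric tracking.
* **Bout detection** — two-state Gaussian hidden Markov model on the log
  windowed RMS envelope, trained by Baum–Welch (initial transitions
  P_switch = 0.9), Viterbi decoding, run-length bout tables and duration
  summaries.
* **Coherence** — DPSS multitaper coherence (120 s windows, 5 s steps,
  NW = 10, K = 19 tapers), phase in degrees (pyloric relative to heart),
  theoretical significance threshold
  `C = sqrt(1 − (α/n)^(1/(K−1)))` with Bonferroni multiplicity `n`, and a
  dataset-level coherent flag (peak above `C` in >50% of windows).
* **Thermal response** — Q10 from ordinary least squares of `log10 F` on
  temperature (`Q10 = 10^(10m)`), and critical ("crash") temperature
  detection from the frequency drop plus a spectral irregularity index.
* **Population statistics** — Pearson correlations, one-way ANOVA,
  Hartigan's dip test of unimodality (exact statistic, Monte-Carlo p), and
  population summary tables.
* **Synthetic data** — quasi-periodic pulse-train heart and two-harmonic
  pyloric channels with programmable coupling phase, Markov bouts,
  Q10-governed temperature ramps with programmed crashes, and a calibrated
  bivariate population generator.

## Worked example

```r
library(ppgrhythms)
cfg <- run_config()

## simulate 10 min of coupled heart + pyloric PPG with inhibitory bouts
params <- synth_params(f_heart = 1.1, f_pyloric = 0.5, coupling = 0.5,
                       coupling_phase_deg = 190, bouts = TRUE,
                       bout_mean_active_s = 120, bout_mean_inhib_s = 30,
                       duration_s = 600, seed = 2)
sim <- gen_baseline(params)
heart   <- preprocess_ts(sim$recording$heart, cfg)
pyloric <- preprocess_ts(sim$recording$pyloric, cfg)

track <- track_peak(spectrogram(heart), cfg$band)
baseline_median(track)            # median peak frequency across windows

feats  <- bout_feature(heart)
states <- decode_states(baum_welch(feats), feats)
bout_durations(states)$summary    # per-state duration summaries

cleaned <- regress_subtract(heart, pyloric)$cleaned
baseline_median(track_peak(spectrogram(cleaned), cfg$band))

coh <- mt_coherence(heart, pyloric)
C <- coherence_threshold(cfg$alpha, cfg$n_tapers, length(coh$window_times))
coherence_summary(coh, C)
```

which prints:

```
baseline heart frequency (Hz): 1.1
  state n mean_s median_s
1     1 5   95.4     90.0
2     0 4   30.5     30.5
pyloric frequency (Hz): 0.498
coherent dataset: TRUE (100% of windows above C = 0.586)
median phase at peak coherence (deg): 190
```

The tracked heart frequency matches the programmed 1.1 Hz; the HMM finds the
four inhibitory bouts this 10 min realization contains (mean 30.5 s against
a generating mean of 30 s); after artifact subtraction the pyloric track
reads the programmed 0.5 Hz even though the 1.1 Hz heart artifact was mixed
in at half amplitude; and the coherence summary recovers the injected
190° phase offset, i.e. the two rhythms are nearly in antiphase.

A thin command-line wrapper over the same functions lives at
`inst/scripts/ppg-pipeline.R` with subcommands `simulate`, `preprocess`,
`spectrogram`, `subtract-heart`, `bouts`, `coherence`, `thermal` and
`population`.

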