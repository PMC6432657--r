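---
title: "Methods: spectral and state-space analysis of dual-rhythm PPG recordings"
author: "ppgrhythms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spectral and state-space analysis of dual-rhythm PPG recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppgrhythms)
```

## The analysis problem

Photoplethysmogram (PPG) sensors glued to a crab's carapace record the
movements of the heart and of the pyloric (stomach) musculature as two
voltage time series sampled at 500 Hz. Both rhythms live in overlapping
frequency ranges (heart roughly 0.3–2.3 Hz, pyloric 0.2–1.6 Hz), the heart
rhythm bleeds into the pyloric sensor as a phase-shifted artifact, the heart
intermittently slows or stops (inhibitory bouts / bradycardia), and both
rhythms speed up with temperature until they "crash" at a critical
temperature. `ppgrhythms` implements the complete analysis chain for such
recordings:

1. conditioning (offset removal, 5 Hz zero-phase Butterworth low-pass,
   decimation to 10 Hz),
2. Burg autoregressive spectrograms and peak-frequency tracking,
3. removal of the heart artifact from the pyloric channel by lagged linear
   regression,
4. two-state hidden Markov model (HMM) segmentation of inhibitory bouts,
   trained by Baum–Welch,
5. time-resolved multitaper (DPSS) coherence with a theoretical significance
   threshold and circular phase summaries,
6. Q10 estimation by log-linear regression of frequency on temperature and
   detection of the critical temperature, and
7. cross-animal statistics (Pearson correlations, one-way ANOVA, Hartigan's
   dip test).

Because no public recordings accompany this kind of experiment, the package
ships a synthetic generator that produces two-channel recordings with all of
the structural features above plus per-sample ground truth, so every stage
is verifiable end to end.

## The synthetic generator and what it emulates

`gen_baseline()` builds the heart channel as a raised-cosine pulse train and
the pyloric channel as an asymmetric two-harmonic oscillation; a scaled,
phase-delayed copy of the heart waveform is mixed into the pyloric channel
(the artifact), and white measurement noise is added to both.

Two design choices deserve emphasis:

* **Quasi-periodicity.** Real motor rhythms wander; a strictly clocklike
  generator produces spectral lines whose Burg pole radii approach the unit
  circle, and the evaluated heights of such lines are numerically fragile
  (see *Numerical choices*). Each channel's instantaneous frequency is
  therefore multiplied by `1 + w(t)` where `w` is a stationary
  Ornstein–Uhlenbeck process (default sd 1%, correlation time 5 s). This is
  the generator's model of the band-limited wander visible in real
  spectrograms. Setting `freq_jitter_rel = 0` and `noise_sd = 0` recovers
  strictly periodic channels (used by the exact-periodicity tests).
* **Waveforms.** The default heart pulse occupies 0.8 of the cycle, matching
  the smooth, nearly sinusoidal pulses that survive a 5 Hz low-pass; the
  second and third harmonics then carry roughly 28× and 600× less power than
  the fundamental. The pyloric waveform keeps a visible second harmonic
  (amplitudes 0.8 and 0.1) to emulate its more complex shape.

Bouts are a two-state continuous-time Markov chain with exponential dwell
times (defaults: active 300 s, inhibitory 30 s). The inhibitory state
multiplies the heart amplitude by `bout_amp_factor` (default 0.1) and the
pyloric frequency by `bout_freq_factor` (default 0.6). Explicit bout
intervals can be injected for worked examples. An optional post-bout
amplitude overshoot is off by default.

Temperature ramps (`gen_ramp()`) hold the baseline temperature, rise
linearly, then hold the final temperature. Below the channel's critical
temperature the instantaneous frequency follows
\(f(T) = f_\mathrm{base}\,Q_{10}^{(T-T_\mathrm{ref})/10}\) (reference 11 °C).
Above it the rhythm "crashes": cycle periods acquire Gaussian jitter
(default sd 0.3 of the instantaneous period), the mean frequency decays back
toward baseline and the amplitude decays toward 20% of its pre-crash value,
both with a 60 s time constant. The jitter is parameterized relative to the
period (an absolute `crash_jitter_sd` in seconds is accepted) because a
fixed absolute jitter would mean very different irregularity at 0.6 Hz and
at 1.6 Hz.

`gen_population()` draws paired baseline frequencies from a Gaussian copula
with uniform marginals on the observed ranges. The latent normal correlation
is set to \(2\sin(\pi r/6)\) so the Pearson correlation of the uniform
marginals equals the requested `r` exactly (the raw copula correlation would
be biased low by about 0.02 at `r = 0.61`).

What the generator does **not** emulate: movement artifacts, sensor drift,
non-exponential (e.g. bimodal) bout-duration distributions, gastric-mill
interference, and amplitude–frequency covariation. Tests passing on this
generator therefore demonstrate correctness of the algorithms under the
stated signal model, not robustness to every pathology of real recordings.

## Spectral estimation

Each conditioned channel is analyzed in 12.8 s windows (128 samples at
10 Hz) with 50% overlap. Per window a Burg AR model of order
`window/4 + 1 = 33` is fitted (reflection coefficients minimizing the summed
forward and backward prediction error; the recursion guarantees a stable
model) and its power spectral density
\(P(f) = \sigma^2 / r \,/\, |1 - \sum_k a_k e^{-2\pi i f k / r}|^2\)
is evaluated on a dense grid. The per-window rhythm frequency is the argmax
of power within a configurable band (default 0.2–2.5 Hz, ties to the lower
frequency), and an animal's baseline frequency is the median across windows.

### Numerical choices

* **Spectral grid.** The AR spectrum of a strong rhythmic component has a
  pole very close to the unit circle; its peak is much narrower than any
  reasonable display grid. On a coarse grid the evaluated height of such a
  peak depends on how close the pole angle lands to a grid point, which can
  (and in practice does) re-order peaks between windows. The default grid is
  therefore dense — 8193 points on [0, 5] Hz, i.e. ~6·10⁻⁴ Hz spacing, with
  the FFT length a power of two — which makes peak ordering stable across
  windows for the waveforms and noise levels the generator produces. The raw
  PSD formula is used unmodified; `ar_psd()` offers an optional evaluation
  bandwidth floor for display smoothing, off by default.
* **Windows.** The window mean is removed before each Burg fit; an
  incomplete trailing window is dropped, not padded. Zero-variance windows
  yield a floor-valued spectrum instead of an error so silent stretches do
  not abort a whole recording.
* **Intrinsic resolution.** With 7–15 cycles per window the peak location
  wobbles by a few millihertz window-to-window even in noise-free signals;
  tests of tracking accuracy use the method's intrinsic scale
  (≈ `1/window` = 0.078 Hz and fractions of it), not the grid spacing.

## Heart-artifact subtraction

The artifact in the pyloric sensor is modelled as a scaled, delayed copy of
the heart signal. The delay is estimated as the integer-sample lag (within
±3 s) maximizing the absolute cross-correlation, ties toward the smallest
magnitude; gain and intercept then come from ordinary least squares of the
pyloric signal on the shifted heart signal, and the scaled copy is
subtracted. For periodic signals the lag is identifiable only modulo the
heart period, which is irrelevant for subtraction (the regression gain
absorbs the alignment). A silent heart regressor returns the input unchanged
with gain 0. One global fit is the default; per-window refits (for drifting
gain during temperature ramps) are available via `fit_window_s`.

## Bout segmentation

The HMM observes the log windowed standard deviation (2 s windows, 1 s
step) of the conditioned heart trace — the envelope collapses during a bout.
The within-window mean is removed before taking the RMS because a
globally offset-removed but amplitude-suppressed stretch otherwise retains a
DC pedestal that masks the collapse. Emissions are one Gaussian per state;
transitions start from the classical fast-switching values
\(P_{AI} = P_{IA} = 0.9\) and are re-estimated by EM. Emission parameters
are initialized from a deterministic two-means split of the feature, which
reliably finds a minority low-amplitude mode. The E step uses a scaled
forward–backward pass; the log-likelihood is asserted non-decreasing at
every iteration and iteration stops at a relative change of 10⁻⁶ or 500
iterations.

Decoding is by Viterbi, with the state of lower emission mean labelled
inhibitory, so results are invariant to state permutation and to affine
rescaling of the feature. Before decoding, the two-state fit is compared by
BIC against a single Gaussian; if one state suffices the record is labelled
all-active — without this guard two overlapping components would happily
split pure noise into spurious 1 s "bouts". Durations come from run-length
encoding of the decoded path times the feature step; no minimum-duration
filter is applied by default (one is available).

## Multitaper coherence

Coherence between the conditioned heart and pyloric channels is computed in
120 s windows stepped by 5 s, using 19 DPSS tapers at time–bandwidth product
NW = 10. Tapers come from the symmetric tridiagonal formulation; their
concentrations are evaluated as quadratic forms with the sinc kernel, and
orthonormality is checked in tests. The coherency is
\(S_{xy}/\sqrt{S_{xx} S_{yy}}\) with taper-averaged spectra; phase is
reported in degrees in [0, 360), pyloric relative to heart, positive
meaning the pyloric signal lags (delaying the pyloric channel by τ gives
+360·f·τ at frequency f). The theoretical significance threshold is
\(C = \sqrt{1 - {\alpha'}^{1/(K-1)}}\) with \(\alpha' = \alpha/n\) after a
Bonferroni correction over `n` comparisons; `n` is an explicit argument
(the CLI defaults it to the number of analysis windows). A dataset counts as
coherent when more than half of its windows exceed the threshold at the
in-band peak; the phase summary is the circular median (an ordinary median
fails at the 0/360 wraparound) over significant windows.

## Thermal analysis

Each spectrogram window is paired with the window-centre temperature by
linear interpolation. Q10 comes from ordinary least squares of
\(\log_{10} F\) on \(T\): \(Q_{10} = 10^{10 m}\); the fit quality is the
squared Pearson correlation. Base-10 logarithms are fixed for
reproducibility — any base gives the identical Q10 under the matching
back-transform, which is asserted in tests. Constant frequency returns
Q10 = 1 with R² reported as 0 and a warning.

The critical temperature is a quantitative surrogate for "the rhythm became
irregular and the frequency decreased": the first temperature at which, for
at least 3 consecutive windows, (a) the tracked frequency falls below 90% of
its running maximum over the rising ramp, and (b) the irregularity index —
the fraction of in-band power within ±0.1 Hz of the tracked peak — falls
below 50% of its baseline median. The baseline is the set of windows within
1 °C of the coolest observed temperature. All four constants are exposed as
arguments. When the criteria never co-occur the result is `NA`
(undetermined), and `analyze_ramp()` then fits Q10 on the full rising ramp,
with a message. The integrated (±0.1 Hz) form of the irregularity index is
deliberate: raw peak *heights* of near-line AR spectra fluctuate strongly
window-to-window, while the local power fraction is stable.

## Population statistics

Pearson correlations use the t transform on n−2 degrees of freedom; one-way
ANOVA is the classical equal-variance between/within mean-square ratio
(two groups reduce to the squared pooled-variance t statistic, asserted in
tests). Hartigan's dip — the sup-norm distance between the empirical CDF
and the nearest unimodal CDF — is computed exactly by bisection on the
radius `d`: a unimodal CDF within `d` of the ECDF exists iff values
\(g_j \in [\max(0, C_j/n - d),\ \min(1, C_{j-1}/n + d)]\) exist at the
distinct sample points (the two-sided limits of the ECDF jumps) forming a
nondecreasing sequence that is convex up to some index and concave from it
on. With both band edges nondecreasing, feasibility reduces to forward
extrapolations of the steepest upper-to-lower band line pairs on each side,
with the greatest convex minorant of the upper band as the witnessing
construction; the mode may sit between sample points, which makes the
convex and concave pieces share exactly one index and requires no slope
matching there. The implementation is validated against hand-derived exact
values (evenly spread samples attain the 1/(2n) floor; two tight pairs of
points approach the two-point distributional limit 1/4) and against an
independent brute-force search over grid-restricted unimodal CDFs at small
n. P-values are Monte Carlo, against uniform samples of the same size
(n_boot = 2000 by default) — the conventional least-favourable unimodal
null; the published interpolation tables are not reproduced.

## Problem sizes used by the test suite

The suite exercises the pipeline at desk scale: 300–600 s baseline
recordings for tracking and coherence, a 2 h bout record for the HMM
pipeline (with a 6 h record in the acceptance checks, matching the long
recordings such bouts require), 90 min temperature ramps, 200-replicate
calibration loops for the population generator, and 1000-replicate null
calibrations for the dip test and the coherence threshold. These sizes keep
every stochastic check well inside its tolerance while the whole suite runs
in minutes.

## Known limitations

* The heart-artifact model is a single global (or piecewise) lag and gain;
  true artifacts may be frequency-dependent. Adaptive cancellation is out of
  scope.
* Bout dwell times are exponential; empirical active-state distributions can
  be bimodal. A mixture option is not enabled by default.
* The crash detector's four constants are a pragmatic operationalization; on
  real data they may need tuning per preparation.
* The coherence significance threshold is theoretical (no jackknife
  intervals), and heavily overlapped windows are counted as-is, so
  "fraction of time coherent" inherits their serial dependence.
* Peak tracking assumes the rhythm's fundamental dominates its harmonics in
  power, which holds for the smooth waveforms of low-passed PPG but would
  need a harmonic-aware tracker for spikier signals.
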