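Package: ppgrhythms
Title: Dual-Rhythm Analysis of Crustacean Heart and Pyloric Photoplethysmogram Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for simultaneous in vivo photoplethysmogram (PPG)
    recordings of the crustacean heart and pyloric rhythms. Provides Burg
    autoregressive spectrogram estimation and peak-frequency tracking, removal of
    the heart-frequency artifact from the pyloric channel by lagged linear
    regression, two-state hidden Markov model detection of inhibitory
    (bradycardia) bouts trained by Baum-Welch, time-resolved multitaper (DPSS)
    coherence with a theoretical significance threshold and phase summaries,
    temperature-coefficient (Q10) regression and critical ("crash") temperature
    detection on temperature-ramp recordings, and cross-animal population
    statistics including Hartigan's dip test. A synthetic two-channel PPG
    generator with ground truth drives verification of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
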