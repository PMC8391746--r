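Package: sqamon
Title: Semisupervised Signal Quality Assessment for Wearable ECG and Respiration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Grades 10-second single-lead ECG and 30-second respiratory
    inductive plethysmography windows from wearable monitors into three
    quality levels (good, acceptable, unacceptable). Feature vectors built
    from distribution moments, adjacent-waveform dynamic time warping
    distances, and spectral power descriptors are scored by a from-scratch
    isolation forest; two thresholds calibrated on a small labeled set map
    the anomaly score to the grades. Includes a synthetic ECG/respiration
    generator with parameterized noise injection and a rule-based labeler
    so the whole pipeline is testable without real recordings, plus an
    arrhythmia false-alarm audit that quantifies alarm suppression by
    quality gating.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
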