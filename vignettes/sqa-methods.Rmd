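---
title: "Signal quality assessment as anomaly detection: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signal quality assessment as anomaly detection: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`sqamon` grades fixed-length observation windows of wearable physiological
signal — 10 s for single-lead ECG, 30 s for respiratory inductive
plethysmography (RIP) — into *good*, *acceptable* and *unacceptable*.
The central assumption is that on a long recording from a working sensor,
poor-quality windows are **few and different**: they are a minority of the
stream and their feature vectors sit away from the bulk. That is exactly
the regime in which an isolation forest isolates points quickly, so the
average isolation depth can serve as a quality axis without any labels at
training time.

The pipeline is:

1. **Conditioning** per window: zero-phase Butterworth band-pass
   (ECG 0.5–40 Hz, RESP 0.05–1 Hz), robust outlier clipping at
   `median ± 5 × scale`, z-normalization. Windows are conditioned
   independently, so streaming and batch processing agree bit for bit.
2. **Features**: 8 (ECG) / 18 (RESP) fixed-order descriptors
   (`feature_names()`), combining population-convention skewness and
   kurtosis, adjacent-beat/breath dynamic-time-warping (DTW) distances,
   beat/breath rhythm statistics and Welch-PSD band-power descriptors.
3. **Scoring**: an isolation forest (2000 trees, subsample ψ = 256) gives
   each window `s = 2^(−E[h]/c(ψ))`, with `c(n) = 2H(n−1) − 2(n−1)/n`.
4. **Calibration**: two thresholds `T1 ≤ T2` are chosen on a small labeled
   validation set by exhaustive accuracy maximization; grades follow the
   half-open rule `s < T1` good, `s < T2` acceptable, else unacceptable.
5. **Application**: per-record quality tracks (merged equal-grade
   intervals) and a false-alarm audit — an arrhythmia alarm whose onset
   falls in a poor interval is counted false.

The anomaly-proportion parameter (5%) is stored in the model as metadata
only. It never binarizes scores: grades come exclusively from the
calibrated thresholds, which is the point of the semisupervised design —
the forest orders windows, a handful of labels place the cut points.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| window length | 10 (ECG) / 30 (RESP) | s | shortest span a human grader can judge; respiration needs several breath cycles |
| sampling rate | 200 (ECG) / 25 (RESP) | Hz | typical wearable rates; configurable everywhere |
| band-pass | 0.5–40 / 0.05–1 | Hz | retains QRS energy and breath waveform while removing drift and mains |
| clip multiplier `k` | 5 | robust scales | clips gross impulses only |
| flatline tolerance | 1e-6 | pre-normalization SD | below this a window is signal loss, graded unacceptable outright |
| `n_trees` | 2000 | — | ensemble large enough that scores concentrate (two seeds differ < 0.02 mean absolute) |
| `psi` | 256 | windows | standard isolation-forest subsample; depth limit `ceil(log2 ψ)` |
| DTW segment length | 64 | samples | beats/breaths resampled to a common support before alignment |
| DTW sentinel | 10 | distance | returned when < 3 beats exist; far above any observed adjacent-beat distance, so unassessable rhythm reads as anomalous |
| refractory / min breath period | 0.25 / 1.5 | s | physiological lower bounds on beat and breath spacing |

## The synthetic generator and what it does (not) show

No public dataset carries this device class's paired ECG + RIP signals with
quality labels, so the package ships a generator that is first-class tested
code, not a fixture. It emulates: quasi-periodic sum-of-Gaussians P-QRS-T
beats on a jittered grid (with ventricular/atrial premature beats as
premature wide/normal templates plus compensatory pause), quasi-sinusoidal
breathing with per-breath period/amplitude jitter and apnea pauses, and
five corruption classes — band-limited baseline wander, mains
interference, broadband EMG bursts, impulse artifacts, and flatline
dropout held at the last value. Every realized noise component is retained,
so each window's ground truth (wander ratio, impulse count, dropout
seconds, regular-waveform fraction, unreadable-beat count) is exact and a
rule-based labeler can grade it deterministically.

The grading rules operationalize the qualitative criteria a human grader
would use. ECG: any signal loss over 2 s, wander at or above the signal
amplitude, more than 2 impulses, or more than 2 beats whose local SNR
against injected high-frequency noise falls below 2 is unacceptable;
any loss up to 2 s, wander above one-third of the signal amplitude, 1–2
impulses, up to 2 low-SNR beats, or a low-intensity EMG burst is
acceptable; pathological beats never degrade the grade. RESP: a regular
waveform (window fraction outside apnea/dropout/EMG spans, with breath
jitter below 0.25) over three-fourths of the window and wander below the
signal amplitude is good; an identifiable rhythm (regular fraction ≥ 1/4)
with loss or breath hold under half the window is acceptable; otherwise
unacceptable. The labeler labels *every* window — there is no analogue of
a human annotation campaign dropping windows on inter-rater conflict, so
synthetic class mixtures are slightly "easier" than human-labeled ones.

Two honest gaps between the generator and reality deserve emphasis.
First, synthetic baseline wander is purely additive and band-limited, so
the 0.5 Hz high-pass removes most of it; real wander co-occurs with
electrode motion, saturation and waveform distortion. Wander-driven poor
windows are therefore the main residual error source on the benchmark, and
benchmark accuracy on wander tiers overstates nothing but should not be
read as field performance. Second, beat morphology variability is far
narrower than in real patients. Passing the end-to-end bars (≥ 0.85 ECG,
≥ 0.75 RESP against rule-based truth) demonstrates that the pipeline's
machinery — features, forest, calibration — recovers a known generative
quality structure; it is an engineering regression bar, not a clinical
performance claim.

## Numerical choices

- **Outlier clip scale.** The usual `1.4826 × MAD` collapses on spike-like
  waveforms: most ECG samples are baseline, so the MAD is nearly zero and
  the clip would saturate every QRS complex. The robust scale used is the
  trimmed half-range `(q(0.995) − q(0.005)) / 4`, which tracks the
  physiological amplitude and still clips impulse artifacts at several
  times the waveform range. Constant windows (zero scale) pass unchanged.
- **Respiratory filter realization.** A single order-4 band-pass at
  0.05–1 Hz on a 25 Hz signal has poles crowded near `z = 1` and is
  numerically fragile on 750-sample windows; the band is realized as an
  order-2 high-pass cascaded with an order-4 low-pass, both applied
  forward-backward (`signal::filtfilt`) for zero phase.
- **Threshold candidates.** `find_thresholds()` searches midpoints of
  adjacent sorted unique scores plus the score range extended by a tiny
  epsilon — every decision-distinct pair is visited, so the search is an
  exact optimum, not a grid approximation. Accuracy over all pairs is
  computed from prefix sums in O(k²) vectorized work. Ties are broken by
  macro-F1, then smallest `T2 − T1`, then smallest `T1`, making the result
  deterministic and order-independent; the extremes make the degenerate
  all-one-grade partitions expressible while keeping thresholds within
  (an epsilon of) the observed score range.
- **Boundary convention.** Intervals are half-open throughout:
  `[T1, T2)` on the score axis, `[start, end)` in quality tracks; a score
  exactly at `T1` is acceptable.
- **Isolation trees.** Split features are drawn uniformly among features
  non-constant at the node; constant nodes terminate as external nodes.
  `c(n)` uses exact harmonic numbers up to n = 1000 and the `ln + γ`
  approximation above (the switchover discrepancy is < 3e-3 and only
  affects external-node adjustments, never tree shape). Features enter the
  forest raw (unstandardized): per-feature uniform splits make the forest
  equivariant to per-feature scaling, so standardization is unnecessary.
  Trees are grown in R with a documented RNG draw order (one `sample.int`,
  one `runif` per node) and traversed in C++; the fit is a pure function of
  the seed.
- **Degenerate inputs.** Flatline windows (SD below tolerance before or
  after conditioning) skip feature extraction, receive a sentinel feature
  vector, and are forced unacceptable regardless of score. Fewer than 3
  detected beats yields the sentinel DTW statistics. Empty alarm lists
  report `NA` proportions rather than 0.

## Design decisions taken where the design was open

- **Feature identities.** The 8/18 feature lists are this package's
  documented choice within the stated categories (moments, adjacent-beat
  DTW, amplitude/rhythm, spectral power); they are recorded in
  `feature_names()` and serialized with names so alternates are drop-in.
- **DTW operates on z-normalized resampled beats** — alignment cost then
  measures shape, not amplitude (amplitude has its own features).
- **Per-window conditioning** (not per-record), so results are independent
  of batch composition and identical under streaming.
- **"Poor quality" in the false-alarm audit** defaults to unacceptable
  intervals only, with a strict mode including acceptable ones —
  acceptable windows still support rate analysis, so gating alarms on them
  would over-suppress.
- **Bigeminy/trigeminy flaggers are omitted**: rule-based detection of
  those rhythms adds nothing to the quality-assessment contribution.
- **Benchmark sizes.** The packaged benchmark uses 800/1200/800 (ECG) and
  500/1200/600 (RESP) train/validation/test windows, validation grade
  mixtures of 87.3/5.5/7.2 % (ECG) and 62.7/24.5/12.8 % (RESP), and a
  training stream with 92 % clean-scenario windows. These sizes keep the
  full pipeline and the 200/600/1000-label × 30-repeat calibration
  protocol comfortably reproducible on one CPU while leaving ≥ 1000
  validation labels for the protocol's largest budget.

## Known limitations

- Readers accept CSV (`time_s,value`); binary waveform containers (WFDB,
  EDF) are out of scope for this package and should be converted upstream.
- The alarm flaggers are deliberately simple documented rules (rate
  thresholds, prematurity vs local median RR, width/amplitude typing);
  they exist to exercise the audit, not to compete with clinical
  arrhythmia detectors.
- Calibration optimizes overall accuracy; under heavy class imbalance the
  acceptable class can collapse into its neighbors (visible in the
  benchmark confusion matrices). Cost-sensitive thresholding is
  deliberately out of scope.
- Scores from forests trained on different training streams are not
  comparable; thresholds must be recalibrated per model.
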