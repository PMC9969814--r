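---
title: "Methods: quantifying postural and longitudinal SCG variability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying postural and longitudinal SCG variability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scgvar)
```

## The problem

Seismocardiography (SCG) measures chest-surface acceleration produced by
cardiac mechanical events — aortic valve opening (AO), closure (AC),
blood momentum changes. Within one subject, beat-to-beat SCG morphology
varies substantially, mostly with the respiratory cycle and with body
posture. For SCG to be useful in longitudinal monitoring one must know
how much of a feature change is attributable to these nuisance sources.
`scgvar` implements a complete chain for quantifying that variability on
ECG-gated SCG beats, together with a synthetic generator that plants a
known ground truth so each stage is testable without human recordings.

## Pipeline model

Each recording is processed as:

1. **Conditioning.** Zero-phase (forward–backward) Chebyshev II band-pass,
   0.5–50 Hz, order-4 band-pass prototype, 40 dB stopband; then an
   order-5 centered moving average. Signals acquired above 1 kHz are
   low-pass filtered and decimated to 1 kHz.
2. **Segmentation.** Pan–Tompkins R detection on the ECG; each beat spans
   `[R − 0.1 s, R_next − 0.1 s)` so consecutive windows tile the record.
   The Q point is the ECG minimum in the 50 ms before R.
3. **Clustering.** Beats are normalized to unit peak amplitude and
   clustered with K = 2 k-medoids under a dynamic time warping (DTW)
   dissimilarity. DTW absorbs the nonlinear stretching that respiratory
   sinus arrhythmia (RSA) induces, which defeats Euclidean comparison of
   unequal-length beats.
4. **Features.** Intra-/inter-cluster distance (mean DTW of each beat to
   its own/opposite medoid), band-energy ratios of the medoid spectra in
   five bands against the 0.5–50 Hz total, PEP (Q→AO) and LVEP (AO→AC)
   read off each medoid and averaged, and per-cluster heart rate.
5. **Statistics.** Paired t tests and Cohen's d (pooled SD) between
   postures; one-way ANOVA across sessions; Bland–Altman agreement.

## Numerical choices

* **Second-order sections.** The 0.5 Hz edge at a 10 kHz sampling rate
  puts poles at |z| > 0.9998; an order-8 transfer function is numerically
  unusable there (it returns NaN), so the Chebyshev II design is built in
  zero-pole-gain form (closed-form analog prototype, band transform and
  bilinear map) and applied as a cascade of biquads. Because the data
  pass through the cascade twice, effective attenuation is doubled and so
  is the passband droop.
* **Edge handling.** The moving average truncates its window at the
  record edges rather than padding. The zero-phase band-pass leaves
  slowly decaying transients within roughly two seconds of the record
  edges (the 0.5 Hz edge settles over seconds); on strictly noise-free
  synthetic data these transients are the only source of non-zero
  morphological variability, and `run_pipeline(..., preprocess = FALSE)`
  is available for already-conditioned input.
* **R detection.** Classic Pan–Tompkins stages with fixed constants:
  5–15 Hz zero-phase band-pass, five-point derivative, squaring, 150 ms
  integration, adaptive dual thresholds, 200 ms refractory, 1.66×RR
  search-back. Two non-classic details matter: candidate peaks must
  dominate their ±200 ms neighbourhood (the integrated QRS hump carries
  band-pass ripple that otherwise over-segments a beat), and an
  above-threshold peak within 360 ms of a beat whose derivative slope is
  below half the previous beat's is discarded as ring-down/T-wave.
  Detections are refined to the raw-ECG maximum within ±75 ms.
* **DTW.** Local cost `|x_i − y_j|`, symmetric unit-weight steps
  {diagonal, up, right}, boundary-to-boundary, Θ(l²) in compiled code.
  No global window by default (beats are 600–1200 samples at 1 kHz and
  the full recursion is affordable); an optional Sakoe–Chiba band is
  provided. These conventions are fixed so the brute-force
  path-enumeration oracle in the test suite can assert exact equality.
* **k-medoids.** Assignment ties go to the lower cluster index; an
  emptied cluster is re-seeded with the beat farthest from the remaining
  medoids; random initialization uses 3 seeded restarts (lowest final
  objective wins) because a single random start occasionally lands in a
  local optimum that splits beats by length rather than regime; a
  deterministic farthest-pair initialization is available. After
  convergence, clusters are relabelled so cluster 1 has the higher mean
  heart rate, making labels comparable across runs.
* **Distances with units.** Clustering runs on normalized beats (shape,
  not amplitude), but the reported intra-/inter-cluster distances are
  evaluated on the un-normalized waveforms against the medoids'
  un-normalized waveforms, so variability carries milli-g units; a
  `normalized = TRUE` flag switches to shape-space distances.
* **Spectra.** The nominal bands 0.5–10, 11–20, 21–30, 31–40, 41–50 Hz
  leave the inter-band hertz unassigned; they are implemented as
  contiguous half-open intervals `[0.5,10.5), [10.5,20.5), …, [40.5,50]`
  so the ratios tile the reference band and sum to one by construction.
  The estimator is a Hann-windowed periodogram zero-padded to the next
  power of two ≥ 4× the medoid length: a rectangular window's sidelobe
  leakage (2–4 % outside a ±5 Hz mainlobe for a ~1 s beat) would spread a
  pure in-band tone across bands, while the Hann window keeps integrated
  leakage well below 1 %.
* **Fiducials.** AO is the largest local maximum in `(R, R+200 ms]`, AC
  in `(R+250 ms, R+450 ms]` — windows bracketing systole at resting heart
  rates, configurable for other regimes. Equal-height maxima resolve to
  the earlier peak; a candidate must reach 5 % of the beat's peak
  amplitude (numerical ripple in an empty window is not a wave complex).
  The Q-point rule (argmin in the 50 ms before R) is the package's own
  fixed choice; boundary-truncated or monotone windows are flagged.
* **Effect sizes.** Cohen's d is reported as an absolute value (symmetric
  in group order); the conventional class bands are closed on the left
  (0.2/0.5/0.8 take the higher class). p-values are two-tailed; no
  multiple-testing correction is applied.

## The synthetic generator

`generate_recording()` emulates exactly the features the chain depends
on, with every planted event returned as ground truth:

* **RR/RSA.** `RR_i = (60/hr_mean)(1 + rsa_depth·sin(2π f_resp t_i))`,
  deterministic; default depth 0.08 at 15 breaths/min, a typical resting
  depth for young adults.
* **ECG.** A narrow positive R deflection (Gaussian, σ = 6 ms) and a
  small negative Q deflection fixed 30 ms before R (within the
  physiologic QR interval).
* **SCG.** Per beat, an AO packet (20 Hz carrier under a Gaussian
  envelope, centred PEP after Q) and a smaller AC packet (30 Hz carrier,
  LVEP after AO), plus respiration-locked baseline wander and white
  noise. Per-beat PEP/LVEP jitter is Gaussian (default SD 2 ms). Packet
  envelopes are evaluated within ±8σ of their centres.
* **Respiration and regimes.** Lung volume is a raised cosine phased so
  the high-lung-volume (HLV) half-cycle coincides with the short-RR half
  of the RSA cycle; flow is its analytic derivative, and the four phase
  labels (LLV/HLV × INS/EXP, zero flow classed as expiration) partition
  each breath. Beat morphology switches between two regimes with the
  phase at the R wave: HLV beats (planted label 1) receive an extra
  low-frequency component after AO, a wider AO packet and a stronger AC
  packet, all scaled by `cluster_mod_depth`. These are shape changes, so
  they survive per-beat normalization, and packet centres are untouched,
  so planted timings remain recoverable. This geometry reproduces the two
  empirical regularities of respiration-clustered SCG: one morphology
  regime occupies the high-volume arc of the breath, and that cluster is
  the faster one.
* **Posture presets.** PEP 70/74/80.6 ms, LVEP 300/286.9/272 ms and mean
  HR 65/68/70 bpm for supine/tilt45/sitting; `simulate_cohort()` adds
  persistent per-subject offsets (SD 3 bpm, 6 ms, 10 ms) so posture
  contrasts are paired within subject, and sessions differ only in the
  noise seed, making the session factor null by construction.

What the generator does **not** emulate: P/T waves and realistic ECG
morphology, hemodynamics (posture enters only through parameter
presets), ectopic beats, sensor placement error, motion artefacts, or
1/f-type instrument noise. Tests passing on this generator certify the
algorithmic chain — segmentation arithmetic, clustering recovery,
fiducial and statistical correctness — not robustness to every artefact
of real recordings.

## Worked example

```{r, eval = FALSE}
cfgs <- simulate_cohort(n_subjects = 6, sessions = 1, duration_s = 60,
                        seed = 1)
feats <- run_pipeline(cfgs)
compare_postures(feats, feature_cols = c("pep_ms", "lvep_ms"))
```

## Test problem sizes

The suite exercises: the DTW oracle exhaustively for all sequence pairs
of length ≤ 4 over {0, 1, 2} plus 2000 seeded pairs of lengths 5–6
(exhaustive length-6 enumeration would be hours of path enumeration for
no added coverage); clustering recovery on four 40 s recordings with
`cluster_mod_depth = 0.6`, `noise_sd = 0.05`; timing recovery on a
6-point PEP × LVEP grid of 30 s recordings; and the longitudinal null on
19 subjects × 5 sessions of 30 s supine recordings. The null check
asserts that the number of nominally significant session ANOVAs does not
exceed the 99 % binomial bound at α = 0.05 — "all rows non-significant"
is not a sound assertion for dozens of independent null tests.

## Limitations

* The clustering assumes exactly two respiration-linked regimes; K > 2
  model selection is out of scope.
* AO/AC windows assume resting heart rates; tachycardia would need the
  configurable windows shifted.
* Intra-/inter-cluster distances are unnormalized DTW path sums, so they
  scale with beat length (sampling rate and RR) as well as amplitude;
  comparisons are meaningful at a fixed sampling rate.
* The statistical layer implements the classical tests only — no
  repeated-measures ANOVA, mixed models, or non-parametric alternatives.
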