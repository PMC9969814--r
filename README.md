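# scgvar

Postural and longitudinal variability analysis of seismocardiographic
(SCG) signals.

SCG records the low-frequency accelerations of the chest wall produced
by cardiac mechanical activity — aortic valve opening (AO) and closure
(AC), blood momentum changes, myocardial contraction. It is attractive
for non-invasive longitudinal monitoring, but beat-to-beat SCG
morphology varies within a subject, chiefly with the respiratory cycle
and with body posture, and that intra-subject variability contaminates
any feature tracked over time. `scgvar` is for researchers in
cardiomechanical signal processing who need to quantify that
variability: it implements the full chain from raw ECG+SCG traces to
respiration-declustered beat groups and posture/session statistics,
together with a synthetic generator with planted ground truth so every
stage is testable without human recordings.

## What it computes

* **R-gated beats.** Pan–Tompkins R detection on the ECG; beat *i* spans
  [R*i* − 0.1 s, R*i+1* − 0.1 s). Signals are conditioned with a
  zero-phase Chebyshev II band-pass (0.5–50 Hz, applied as second-order
  sections), an order-5 moving average, and decimation to 1 kHz.
* **Respiration declustering.** Beats normalized to unit peak are
  clustered with K = 2 k-medoids under the dynamic time warping (DTW)
  dissimilarity, with the medoid update

  C_j = argmin_{y ∈ cluster j} Σ_i dtw(y, X_ij),

  iterated to a label fixpoint. DTW absorbs the beat-length variation
  that respiratory sinus arrhythmia (RSA) induces.
* **Morphological variability.**

  intra = (1/(n₁+n₂)) [ Σ dtw(C₁, X_i1) + Σ dtw(C₂, X_i2) ]
  inter = (1/(n₁+n₂)) [ Σ dtw(C₂, X_i1) + Σ dtw(C₁, X_i2) ]

  evaluated on the un-normalized (milli-g) beats.
* **Spectral distribution.** Medoid band energies in 0.5–10, 11–20,
  21–30, 31–40, 41–50 Hz relative to the 0.5–50 Hz total, averaged over
  the two medoids.
* **Cardiac timing.** PEP = Q→AO and LVEP = AO→AC read off each medoid
  and averaged; per-cluster heart rate (cluster 1 is, by convention, the
  faster cluster).
* **Statistics.** Paired t (t = μ√n/σ on the paired differences),
  Cohen's d with pooled SD
  (σ_pooled = √[((n₁−1)σ₁² + (n₂−1)σ₂²)/(n₁+n₂−2)]), one-way ANOVA
  across sessions, Bland–Altman bias ± 1.96·SD limits of agreement.

## Worked example

```r
library(scgvar)
cfgs  <- simulate_cohort(n_subjects = 6, sessions = 1, duration_s = 60,
                         seed = 1)
feats <- run_pipeline(cfgs)
feats[1:3, c("posture", "n_beats", "intra_mg", "inter_mg",
             "pep_ms", "lvep_ms", "hr_c1", "hr_c2")]
#>   posture n_beats intra_mg inter_mg pep_ms lvep_ms hr_c1 hr_c2
#> 1  supine      61    15.34    28.33   74.0   294.5 66.68 60.16
#> 2  tilt45      64    15.27    28.82   76.0   280.5 69.77 62.99
#> 3 sitting      66    14.96    29.23   83.5   266.5 71.89 64.90
```

Each row is one (subject, posture, session) recording: intra-cluster
variability is well below inter-cluster variability (the two
respiration-linked morphology regimes separate), PEP lengthens and LVEP
shortens from supine to sitting (the planted posture presets are
70/300, 74/286.9 and 80.6/272 ms), and cluster 1 carries the higher
heart rate, as expected when the clusters track the respiratory cycle.

```r
compare_postures(feats, feature_cols = c("pep_ms", "lvep_ms"))
#>       comparison feature n_pairs      t df  p_value cohens_d effect_class
#> 1  supine-tilt45  pep_ms       6  -6.53  5 1.26e-03     1.13   very large
#> 2  supine-tilt45 lvep_ms       6  13.09  5 4.64e-05     1.14   very large
#> 5 supine-sitting  pep_ms       6 -18.19  5 9.24e-06     2.77   very large
#> 6 supine-sitting lvep_ms       6  51.69  5 5.12e-08     2.56   very large
```

Within-subject pairing makes the posture contrasts sharp even at six
synthetic subjects. `compare_sessions()` produces the analogous one-way
ANOVA table across recording sessions.

A command-line wrapper with `simulate` / `run` / `compare-postures` /
`compare-sessions` verbs is installed at `inst/scripts/scgvar-cli.R`.

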