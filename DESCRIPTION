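Package: scgvar
Title: Postural and Longitudinal Variability Analysis of Seismocardiographic Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying intra-subject variability of
    seismocardiographic (SCG) chest-acceleration signals across body
    postures and longitudinal recording sessions. Provides a synthetic
    ECG+SCG generator with respiratory sinus arrhythmia and planted
    respiration-linked beat morphology regimes, zero-phase Chebyshev II
    band-pass preprocessing, Pan-Tompkins R-peak detection and R-gated
    beat segmentation, shape-based K-medoid clustering of beats under a
    dynamic time warping (DTW) dissimilarity, morphological, spectral and
    cardiac-timing (PEP/LVEP) features, and the paired-t / Cohen's d /
    one-way ANOVA / Bland-Altman statistical layer used to compare
    features between postures and across sessions.
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
    testthat (>= 3.0.0)
Config/testthat/edition: 3
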