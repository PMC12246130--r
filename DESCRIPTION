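Package: stnlfp
Title: Consistency Analysis of Subthalamic LFP Physiomarkers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of subthalamic local field potential (LFP)
    physiomarkers for adaptive deep brain stimulation: simulation of
    Percept-like bipolar STN-LFP recordings with known ground truth, a
    five-step artifact-suppression chain (zero-phase high-pass, spectral
    Hampel filters, notch filters, SVD-based ECG beat-template subtraction),
    Welch spectral estimation, decomposition of power spectra into periodic
    (Gaussian peak) and aperiodic (offset/exponent) components, beta-peak
    tracking across visits with stimulation-responsiveness scoring, and a
    reliability-statistics layer (intraclass correlation with absolute
    agreement, repeated-measures ANOVA with sphericity handling, paired
    parametric and exact nonparametric tests with effect sizes).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
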