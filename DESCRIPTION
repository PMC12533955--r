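Package: fxeeg
Title: EEG Biomarker Pipeline for Mouse Models of Fragile X Syndrome
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for epidural EEG biomarkers used in Fmr1
    knockout mouse studies: resting power spectral density with canonical
    band binning (theta through high gamma), Morlet-wavelet time-frequency
    decomposition with inter-trial phase coherence (ITPC) and
    baseline-corrected single-trial power (STP) for sound-evoked paradigms
    (noise-burst trains, 40 Hz auditory steady-state response, 1-100 Hz
    upsweep chirp), a Monte Carlo cluster-based permutation test on binned
    time-frequency matrices, and movement-covariate-adjusted band-power
    statistics with Bonferroni control. Includes a synthetic-EEG generator
    with known ground-truth effect parameters (1/f background, band-limited
    oscillations, controllable gamma elevation and phase-locking fraction)
    for calibration and parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    signal,
    car,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
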