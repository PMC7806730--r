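Package: oculodem
Title: Eye-Movement Analysis of the Digital Developmental Eye Movement Test
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested pipeline for analysing gaze recordings made while
    children perform the digital Developmental Eye Movement (DEM) test.
    Covers the stimulus geometry and photometry of the digital DEM,
    preprocessing of irregularly sampled gaze streams (median prefilter,
    500 Hz resampling, zero-phase Butterworth low-pass, noise-robust
    differentiation), adaptive MAD-threshold saccade detection and fixation
    parsing, segmentation of reading scanpaths into number-identification
    and return-sweep epochs with per-epoch oculomotor metrics, DEM scoring
    (error-adjusted horizontal time, ratio, naming percentage) and
    reaction-time cleaning for speed-acuity tasks, the statistical
    machinery (Pearson and partial correlations, Williams' test for
    dependent correlations, FDR, power and sample-size computations), and
    a synthetic gaze-and-reaction-time cohort generator with full ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
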