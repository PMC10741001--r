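Package: ppgcalib
Title: Calibration-Interval Hypertension Screening from Photoplethysmogram Scalograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for discriminating normotensive from
    hypertensive subjects using photoplethysmogram (PPG) recordings. Paired
    PPG/arterial-pressure waveforms are labeled by mean systolic peak pressure
    against a 130 mmHg threshold, band-pass filtered, downsampled, segmented
    into 10-second windows, and converted to analytic Morse-wavelet scalogram
    images with the cone of influence marked. Train/validation splits follow a
    calibration-interval design (under 1 h, 1-6 h, 6-24 h, over 24 h between
    calibration and test measurements) with odd/even chain parity, and a small
    convolutional network trained with Adam and early stopping classifies the
    images. A synthetic timestamped PPG/ABP cohort generator with
    class-dependent pulse morphology and optional slow blood-pressure drift
    makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    png,
    pracma,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    viridisLite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
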