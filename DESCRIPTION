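Package: wearecg
Title: Single-Lead Wearable ECG Simulation, Conditioning, Delineation and Exercise-Intensity Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A tested pipeline for single-lead wearable ECG analysis: a
    synthetic ECG generator with analytic per-beat ground truth (Gaussian
    wave model with LF/HF-modulated RR series and configurable powerline,
    baseline-wander and broadband noise), digital signal conditioning
    (twin-T-derived 50 Hz notch and Hamming-window FIR low-pass),
    derivative-based fiducial-point delineation, interval and
    heart-rate-variability feature extraction (SDNN, LF and HF band power),
    and a small fully connected neural-network classifier of exercise
    intensity with dropout and patience-based early stopping, plus
    permutation feature importance and agreement/SNR metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    zoo,
    stats,
    utils,
    jsonlite,
    yaml,
    rlang
Suggests:
    testthat (>= 3.0.0),
    nnet
Config/testthat/edition: 3
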