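Package: musupp
Title: Mu-Rhythm Suppression and EMG Muscle-Fatigue Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for quantifying EEG mu-rhythm suppression and
    surface-EMG muscle fatigue in before/after rehabilitation designs. Covers
    edge trimming, zero-phase Hamming windowed-sinc high-pass filtering,
    artifact subspace reconstruction (ASR) with geometric-median calibration,
    amplitude and kurtosis epoch rejection, Welch band-power and relative power
    spectral density ratios over theta/mu/beta/gamma bands, force-threshold EMG
    onset detection with median power frequency and RMS fatigue indices, and a
    paired statistical layer with an exact Wilcoxon signed-rank test. Includes
    synthetic EEG/EMG generators with known ground truth so every stage is
    verifiable by parameter recovery, plus EDF and CSV readers and writers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
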