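Package: imcoh
Title: Imaginary-Coherence EEG Connectivity with Cluster-Based Permutation Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline for phase-based sensorimotor EEG connectivity.
    Simulates multichannel EEG with phase-lagged oscillatory sources and known
    coupling ground truth, preprocesses and epochs continuous recordings,
    performs complex Morlet wavelet time-frequency decomposition, estimates
    imaginary coherence between electrode clusters (resting-state and
    movement-locked, with baseline correction and band/period aggregation),
    extracts per-trial peak beta frequencies, and relates inter-individual
    frequency differences to connectivity change maps via cluster-based
    permutation tests using Spearman rank correlation. Reads and writes EDF+
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
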