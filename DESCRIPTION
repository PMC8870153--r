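Package: stopERSP
Title: Simulation and Cluster-Based Analysis of Stop Signal Task EEG
    Spectral Perturbations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to simulate an anticipated-response stop signal task
    (staircase-tracked stop signal delay, horse-race subject model,
    means-method SSRT), to generate per-region single-trial source EEG
    with controlled band-limited event-related power changes, and to
    analyse the result: complex Morlet wavelet time-frequency
    decomposition with decibel baseline normalization, a trial-pooled
    permutation cluster-mass statistic with multi-region corrected
    thresholding, and cluster-masked power versus clinical-score
    correlation analysis with false discovery rate correction.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
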