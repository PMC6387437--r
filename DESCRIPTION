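Package: eegqc
Title: Quality Assessment of Single-Channel EEG Segments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Classification-based quality assessment for single-channel
    electroencephalography (EEG). One-second segments are screened by
    deterministic saturation/amplitude rules, described by time-domain,
    spectral and entropy features, reduced with the fast correlation-based
    filter (symmetrical uncertainty), and assigned to low, medium or high
    quality by linear discriminant analysis, linear one-vs-one support
    vector machines, or (distance-weighted) k-nearest neighbours. Medium
    quality segments are further screened for muscular (EMG) contamination
    with an Itakura spectral distance against a clean-EEG reference
    spectrum. Includes an SNR-controlled simulator of ocular, muscular and
    extreme-value artefacts superimposed on surrogate resting EEG, plus
    cross-validated evaluation utilities (per-class accuracy, one-vs-rest
    ROC AUC, neighbour-count and SNR sensitivity sweeps, and a
    percentile-threshold baseline detector).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    signal,
    stats,
    utils
Suggests:
    jsonlite,
    MASS,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
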