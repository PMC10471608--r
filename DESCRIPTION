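Package: sighsort
Title: Burst Detection and Sigh Classification for Respiratory Rhythm
    Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Signal-analysis pipeline for respiratory rhythm recordings
    from the preBotzinger complex and for diaphragm EMG.  Detects
    inspiratory bursts in integrated traces by topographic peak
    prominence, locates burst onsets, rejects artifacts, and extracts
    fixed-length burst shapes.  Separates optogenetically evoked "sigh
    attempts" from eupneic bursts with an unsupervised dual-gate
    classifier (PCA shape featurization, minimum-covariance-determinant
    robust scatter, Mahalanobis distance thresholding, and an amplitude
    percentile criterion), labels sighs in vivo with a rolling
    median-absolute-deviation rule, and analyses ROI calcium fluorescence
    (z-scoring, autocorrelation rhythmicity detection, drug-epoch
    activity change, and sigh-triggered statistics).  A synthetic-data
    generator produces ground-truth-labeled population, EMG, evoked-sweep
    and ROI recordings with the statistical structure the analysis
    assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
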