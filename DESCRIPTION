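Package: somnphen
Title: Sleep Phenotyping from Nocturnal Polysomnography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computational phenotyping of central disorders of hypersomnolence
    from staged nocturnal polysomnography. Derives 330 sleep features from a
    hypnogram, a single C3 EEG channel and an optional hypnodensity matrix
    (whole-night and quarter-night hypnogram metrics, stage-transition
    probabilities, artifact-screened multitaper band powers, sleep-spindle and
    slow-oscillation coupling metrics, and hypnodensity mixture/entropy
    features). Provides a Monte-Carlo random-forest evaluation framework with
    SMOTE-balanced cross-validated tuning, impurity-importance feature
    ranking and top-feature selection, and a within-group k-means clustering
    framework with Calinski-Harabasz model selection and Benjamini-Hochberg
    corrected cluster comparison. Includes a synthetic cohort generator with
    known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    ranger
Suggests:
    testthat (>= 3.0.0),
    mclust,
    pROC,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
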