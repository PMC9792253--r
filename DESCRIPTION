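Package: bnnsmote
Title: Borderline Nearest-Neighbour SMOTE and a Lightweight 1D Network for
    Imbalanced EEG Seizure Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for the imbalanced classification problem in scalp-EEG
    seizure detection. Implements the borderline nearest-neighbour synthetic
    minority oversampling technique (BNNSMOTE) -- noise filtering, boundary
    majority identification, hard-to-learn minority set construction and
    interpolation-based synthesis -- together with four reference resamplers
    (random oversampling, SMOTE, Borderline-SMOTE and SVM-SMOTE) on a shared
    exact k-nearest-neighbour backend.  Ships an EEG preprocessing chain
    (Butterworth bandpass, sliding-window segmentation, one-way ANOVA channel
    selection), a declarative one-dimensional MobileNet-style architecture
    with analytic parameter and multiply-add accounting plus a self-contained
    trainer, a leakage-safe stratified cross-validation protocol with
    confusion-matrix metrics, synthetic ground-truth generators for both
    point-cloud and EEG fixtures, and EDF/CSV/JSON input-output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
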