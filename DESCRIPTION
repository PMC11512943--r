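Package: eegensemble
Title: Deep Ensembles with Uncertainty-Aware Epoch Rejection for EEG Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Subject-level binary classification of multi-channel EEG with
    compact convolutional networks and deep ensembles, plus selective
    prediction through variance-based rejection of uncertain epochs. Provides
    a synthetic-cohort generator with class-specific band-limited spectral
    effects, the standard EEG cleaning and segmentation rules (channel
    standard-deviation quality control, recording rejection, inverse-distance
    channel interpolation, zero-phase band-pass filtering, canonical
    frequency-band decomposition, 2-second epoching), Inception-style and
    EEGNet-style classifiers trained with early stopping and learning-rate
    scheduling, five ensemble construction strategies (weight randomization
    with uniform or normal initializers, depth ensembles, Monte Carlo dropout
    over an appended dense-plus-dropout head, heterogeneous model pools, and
    per-frequency-band ensembles), epoch- and subject-level majority voting,
    stratified five-fold cross-validation with rank-based AUC, and
    rejection-curve / error-decrease summaries of the uncertainty procedure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
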