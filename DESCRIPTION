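Package: eegtcn
Title: Seizure Detection from EEG with a Self-Attentive Temporal Convolutional Network
Version: 0.1.0
Authors@R: person("EEG", "Methods Lab", email = "maintainer@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline for automatic detection of epilepsy from
    multichannel resting-state EEG. Provides a seeded simulator of surrogate
    clinical (19-channel, 500 Hz) and single-channel benchmark-style EEG with
    controllable interictal spike-and-wave and ictal content; zero-phase
    Butterworth-style preprocessing with downsampling, non-overlapping 2 s
    segmentation and per-channel min-max normalization; a temporal
    convolutional network with causal dilated convolutions, residual blocks
    and a scaled dot-product self-attention layer (plus TCN, self-attention
    and CNN baselines) trained by plain SGD with cross-entropy; subject-wise
    grouped train/test splitting and k-fold cross-validation; and a
    segment-based evaluation suite (confusion matrices, sensitivity,
    specificity, precision, F1, accuracy, fold-averaged ROC/AUC,
    per-participant accuracy, cohort descriptive tests). All neural-network
    forward and backward passes are implemented on base matrix operations, so
    runs are deterministic given a seed.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    data.table
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
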