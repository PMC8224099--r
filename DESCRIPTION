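Package: pcgfusion
Title: Multi-Domain Feature Fusion of Multi-Channel Heart Sound Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for detecting coronary artery disease from
    five-channel phonocardiogram (PCG) recordings. Provides a synthetic
    multi-channel heart sound generator with ground-truth cardiac-state
    annotations and a controllable disease signature (diastolic/systolic
    murmur energy in the 200-800 Hz band and inter-channel dyssynchrony),
    Butterworth/notch preprocessing with segment quality gating,
    envelope-based cardiac state segmentation, extraction of 270
    time-domain, frequency-domain, entropy (sample, fuzzy, distribution)
    and cross-entropy (cross-sample, cross-fuzzy, joint-distribution)
    features per 10-second segment, feature ranking by information gain and
    SVM recursive feature elimination, and subject-wise cross-validated SVM
    evaluation of single- and multi-channel feature sets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    e1071,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
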