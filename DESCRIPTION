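Package: postsway
Title: Postural Sway Stabilogram Analysis and Instability Detection from
    Wearable Accelerometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to detect potentially unstable postural status from
    tri-axial trunk accelerometer recordings. Reconstructs antero-posterior
    and medio-lateral stabilogram displacements from gravity-referenced
    accelerations, extracts time-domain sway features (displacement extrema,
    RMS path increment, 95% confidence ellipse area) and discrete-wavelet
    features (level-wise mean, standard deviation and energy of detail
    coefficients), and compares three classifiers: a ROC-calibrated
    per-feature threshold voting rule, a Sugeno neuro-fuzzy inference system
    trained by hybrid least-squares/gradient descent on the time features,
    and the same neuro-fuzzy engine fed with wavelet features. Includes
    per-prediction reliability indexes, a range-of-influence sweep for the
    fuzzy rule base, an additive feature-noise robustness protocol, and a
    seedable rig simulator generating labelled sway patterns for end-to-end
    evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    pROC,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
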