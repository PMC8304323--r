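Package: nirslearn
Title: Classifying Memory Encoding and Retrieval States from fNIRS Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for functional near-infrared spectroscopy
    (fNIRS) studies of episodic memory under stress: simulation of
    protocol-structured multichannel fNIRS sessions with known ground truth,
    preprocessing of raw light intensities to oxygenated/deoxygenated
    hemoglobin concentration changes via the modified Beer-Lambert law
    (optical-density conversion, zero-phase Butterworth filtering,
    spline-based motion-artifact correction, wavelet despiking), sliding-window
    extraction of a 651-dimensional temporal and functional-connectivity
    feature representation, classifier selection across eleven model families
    with ANOVA-F feature ranking, randomized hyperparameter search and
    participant-grouped cross-validation, condition-group transfer evaluation,
    and noise-replacement permutation importance aggregated onto brain
    regions of interest.
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
    yaml,
    MASS,
    class,
    e1071,
    kernlab,
    rpart,
    ranger,
    xgboost,
    glmnet
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
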