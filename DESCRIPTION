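Package: ramantissue
Title: Raman Spectral Preprocessing and Tissue Classification Pipelines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for binary tissue classification from Raman spectra:
    SNIP baseline correction, L2 and standard-normal-variate normalization,
    median and Savitzky-Golay/Gaussian smoothing, principal-component
    dimensionality reduction, patient-grouped cross-validation (including
    leave-one-patient-out), classical machine-learning and compact
    one-dimensional convolutional / residual network classifiers, a
    preprocessing ablation harness, Grad-CAM saliency for one-dimensional
    signals, and a patient-structured synthetic cohort simulator for
    end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    signal,
    xgboost,
    randomForest,
    e1071,
    glmnet
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
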