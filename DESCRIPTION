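Package: scatteromics
Title: Machine Learning on Multimodal Quantitative-Ultrasound Envelope Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for tissue characterization from beamformed ultrasound
    radiofrequency data using envelope statistics. Computes sliding-window
    parametric images of the Nakagami shape parameter, the homodyned-K
    scatterer clustering parameter and coherent-to-diffuse ratio, and
    histogram-based Shannon entropy; extracts a compact 13-statistic
    first-order feature set per parametric map; performs LASSO feature
    selection with Spearman-correlation pruning; and fits SVM, random forest
    and linear discriminant classifiers under repeated stratified
    cross-validation with Youden thresholding, calibration analysis and a
    full diagnostic-metric panel. A built-in point-scatterer phantom
    simulator generates labeled cohorts with known ground-truth envelope
    statistics for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    MASS,
    glmnet,
    e1071,
    randomForest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
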