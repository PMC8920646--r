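Package: qustc
Title: Quantitative Ultrasound Descriptors for Breast Lesion Characterization
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Extracts the three major families of intratumoral quantitative
    ultrasound (QUS) descriptors from radiofrequency (RF) echo data: spectral
    parameters (midband fit, spectral slope, spectral intercept from
    sliding-window linear spectral fits with attenuation correction), envelope
    statistics (Nakagami shape/scale and derived effective cross-section;
    homodyned-K coherent-to-diffuse ratio, effective scatterer number and
    diffuse-to-total power ratio estimated from fractional-order moment
    statistics), and gray-level co-occurrence texture features. Includes a
    synthetic RF generator with known ground truth, SMOTE and Tomek-link
    hybrid resampling for imbalanced lesion tables, sequential forward
    feature selection, and classifier evaluation (KNN, linear SVM, random
    forest) under holdout, stratified k-fold and leave-one-out validation
    with ROC/AUC reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    signal,
    e1071,
    randomForest,
    pROC
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
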