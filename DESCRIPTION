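Package: radresp
Title: Multi-Lesion CT Radiomics and Ensemble Prediction of Chemotherapy Response
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for predicting volumetric response of multi-site ovarian
    cancer to neoadjuvant chemotherapy from baseline CT imaging, clinical
    records and blood biomarkers. Extracts per-lesion radiomics (shape,
    first-order, intensity-volume histogram and Haralick texture features)
    from multi-label segmentation masks, including rim and peripheral ratio
    feature families computed on physically eroded and dilated lesion
    contours; assembles per-patient feature tables with encoded clinical
    variables and a log-volume-ratio response endpoint; fits an ensemble
    regressor combining an elastic net, an RBF support vector regressor and
    a random forest under repeated cross-validated randomised hyperparameter
    search; and provides validation metrics, feature-importance reports and
    imaging-feature cluster analyses. Includes synthetic phantom-image and
    cohort generators so the full pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    glmnet,
    e1071,
    ranger,
    mclust,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
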