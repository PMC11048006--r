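Package: subgrade
Title: Sub-Region Radiomics and Machine Learning for Binary Tumour Grading
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline for grading renal tumours from 3D CT volumes
    using intra-tumoural sub-region radiomics. Decomposes a binary tumour mask
    into volume-fraction cores and hollow-rim peripheries via an anisotropic
    Euclidean distance transform, computes a standardised radiomics feature
    battery (first-order, GLCM, GLRLM, GLSZM, GLDM, NGTDM, 3D shape, plus
    filtered-image variants), performs leakage-safe z-scoring, correlation
    filtering, gradient-boosting feature selection and SMOTE class balancing,
    trains an eleven-classifier model grid with internal and external
    validation, and evaluates predictions with confusion-matrix metrics
    (MCC, F1, balanced AUC, McNemar and chi-squared tests). Includes a seeded
    synthetic CT phantom and cohort generator so the whole analysis is testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    withr,
    digest,
    e1071,
    ranger,
    xgboost,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
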