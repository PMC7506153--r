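Package: radstage
Title: PET/MR Radiomics Staging Models with Metabolic Correlates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for tumour-staging radiomics on co-registered
    PET and MR volumes: isotropic resampling and 0-255 grey normalisation, a
    396-feature catalogue (histogram, shape, Haralick, grey-level co-occurrence
    and run-length families at voxel offsets 1, 4 and 7), PET metabolic
    parameters (SUVmax, metabolic tumour volume at a 40 percent SUVmax
    threshold, total lesion glycolysis), minimum-redundancy maximum-relevance
    plus L1-penalised logistic feature selection, radscore staging models with
    ROC and calibration diagnostics, and Pearson correlation of selected
    features against metabolic parameters. A deterministic phantom-cohort
    generator makes every stage testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    glmnet,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
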