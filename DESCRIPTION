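Package: PanelCascade
Title: Stability-Based Selection of Multi-Marker Diagnostic Panels
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Discovery of multi-marker serum-protein diagnostic panels for
    case-control studies, modelled on pancreatic ductal adenocarcinoma
    screening. Provides exhaustive enumeration of marker subsets, a uniform
    fit/score contract over five classification algorithms (logistic GLM,
    ridge-penalized logistic regression, support vector machine, random
    forest, and the GLM+RF score average), stratified cross-validated AUC
    estimation, operating points at a fixed target specificity with
    stage-stratified sensitivity, and a stability-based selection cascade
    (top-ranked fraction, mandatory-marker containment, train/validation
    AUC-gap filter, cross-algorithm min-AUC pick) with a full audit ledger.
    A synthetic case-control cohort generator with planted marker effects
    provides a recoverable ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0), SummarizedExperiment
Imports: methods, stats, utils, tools, S4Vectors, glmnet, e1071, ranger,
    jsonlite, yaml
Suggests: testthat (>= 3.0.0), withr, pROC, optparse
Config/testthat/edition: 3
biocViews: Classification, BiomedicalInformatics, Proteomics,
    StatisticalMethod
RoxygenNote: 7.3.3
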