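Package: mitoCombine
Title: Exhaustive Evaluation of Classifier Combinations for
    Mitochondrial Localization Prediction
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to evaluate how combinations of protein
    subcellular-localization predictors perform when their outputs are fused
    by a support vector machine. Provides a labelled feature-table container
    built on SummarizedExperiment, exhaustive enumeration of predictor
    subsets, repeated stratified train/test resampling with a
    support-vector-fraction overfitting gate, sensitivity/specificity/FDR
    statistics including a class-prior-corrected false discovery rate,
    combination ranking, per-tool contribution-probability analysis, and a
    seeded synthetic-data generator emulating a mitochondrial versus
    non-mitochondrial protein classification study with heterogeneous,
    correlated and low-coverage predictors.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    parallel,
    data.table,
    e1071,
    S4Vectors,
    SummarizedExperiment
Suggests:
    kernlab,
    jsonlite,
    withr,
    testthat (>= 3.0.0),
    knitr
biocViews: Classification, Proteomics, Software, SupportVectorMachine
Config/testthat/edition: 3
RoxygenNote: 7.3.3
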