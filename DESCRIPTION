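Package: lungReporter
Title: Multi-Task Semantic Classification of Lung Nodules and Structured
    Report Generation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Maps a 113-dimensional radiomics/segmentation feature vector of
    a lung nodule to three semantic labels (Location, Texture, Margin) with a
    jointly trained multi-objective neural network, assigns a Lung-RADS
    category through a configurable rule table, and renders a structured
    radiology report by template slot filling. Includes a synthetic cohort
    generator with class-conditional feature structure and phantom
    segmentation stacks, slice-information (SISN) features, and evaluation
    utilities (macro precision/recall/F1, ROC/AUC, leave-one-out
    cross-validation).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'labels.R'
    'registry.R'
    'cohort.R'
    'model.R'
    'evaluation.R'
    'lungReporter-package.R'
    'lungrads.R'
    'reporting.R'
    'pipeline.R'
    'sisn.R'
    'synthetic.R'
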