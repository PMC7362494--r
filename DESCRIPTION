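Package: qsarwolf
Title: Grey-Wolf Descriptor Selection and Artificial-Immune-System
    Classifiers for QSAR Duration-of-Action Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative structure-property (QSAR) modelling of
    drug compounds described by large molecular-descriptor tables, developed
    around the sulfonamide duration-of-action problem (short, medium, long
    acting).  Provides constitutional descriptors computed from SMILES
    strings, a grey-wolf-optimization (GWO) wrapper for selecting informative
    descriptors, three artificial-immune-system classifiers (the artificial
    immune recognition system AIRS, clonal selection CLONALG, and an
    immune-network model that classifies by minimal SVD binding energy),
    a synthetic descriptor-table generator, an evaluation harness with
    ROC/AUC, lift charts and the standard confusion-matrix panel, baseline
    classifier adapters, and a reproducible end-to-end pipeline with run
    manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    randomForest,
    readr,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
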