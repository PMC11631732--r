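Package: dualtaa
Title: Dual Tumor-Associated Antigen Screening and Cross-Modality Validation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for discovering and validating pairs of
    tumor-associated antigens (TAAs) suitable for dual-targeting therapies.
    Covers single-cell RNA-seq quality control, counts-per-million log
    normalization, highly variable gene selection, PCA and ridge batch
    regression; random-forest ranking of genes separating malignant from
    normal cells with a surfaceome intersection; expressing-cell-fraction
    and per-patient co-expression statistics for an anchor/partner gene
    pair; immunohistochemistry H-score quantification and co-positivity
    calls; ROC/Youden calibration of RNA thresholds against IHC labels;
    cohort single- and dual-positivity coverage estimation; and
    Kaplan-Meier/log-rank survival stratification of dual-expression
    groups. Ships synthetic-data generators with known ground truth for
    every input modality, so the whole workflow is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    ranger,
    survival,
    jsonlite
Suggests:
    pROC,
    yaml,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
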