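Package: cafatlas
Title: Cancer-Associated Fibroblast Atlas Analysis Pipeline for Skin Cancer scRNA-seq and In Situ Quantification
Version: 0.1.0
Authors@R:
    person("Atlas", "Maintainers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: Re-implements, as a tested and reusable pipeline, the computational
    procedures used to characterise cancer-associated fibroblast (CAF) subtypes
    in skin cancer from Smart-seq2 single-cell RNA-seq and in situ marker
    imaging: cell quality filtering and log-normalization of RPKM matrices,
    copy-number-based malignancy calling from smoothed relative expression,
    rank-sum marker derivation and bin-matched module scoring, a
    permutation-null ligand-receptor enrichment test with a donor co-presence
    prerequisite, and ROI-based CAF density quantification with T-cell
    exclusion regression. A synthetic-data generator with planted ground truth
    stands in for restricted patient data so every stage is testable offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    matrixStats,
    stats,
    utils,
    jsonlite,
    yaml,
    digest
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
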