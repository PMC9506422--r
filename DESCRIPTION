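Package: sclcsubtyper
Title: Proteomic Subtype Characterization of Small-Cell Lung Cancer Cell Lines
Version: 0.1.0
Authors@R:
    person("SCLC", "Proteomics", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for multi-omic subtype characterization
    of small-cell lung cancer (SCLC) cell-line proteomes. Covers preprocessing of
    label-free intensity matrices (log2 transform, median normalization, replicate
    aggregation, valid-value filtering, batch-effect regression, left-censored
    normal imputation, on/off protein detection), neuroendocrine (NE) and
    epithelial-mesenchymal transition (EMT) signature scoring, ANOVA/Tukey-based
    subtype-specific protein selection, over-representation analysis, pre-ranked
    and single-sample gene set enrichment with a subtype-characteristic filter and
    cross-omics concordance rule, consensus clustering with silhouette-based K
    selection, principal variance component analysis, sparse PLS discriminant
    marker selection, and database-overlap / drug-sensitivity annotation. Includes
    a synthetic-data generator with planted ground truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    cluster,
    matrixStats,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
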