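Package: PancScreen
Title: Scoring and Integration of Pooled CRISPR Drug-Resistance Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis of genome-wide pooled CRISPR knock-out and activation
    drug-resistance screens starting from sgRNA count tables: counts-per-million
    normalization, guide-level quality filtering, per-replicate log2 fold
    changes, the replicate-minimum "L2FC sum" gene resistance statistic,
    multi-drug and cross-cell-line aggregation, rank-stratified Wilcoxon
    pathway enrichment, an expression-weighted drug-sensitivity score (PancDS),
    and integration with patient survival via Cox proportional hazards and
    log-rank stratification. Includes a negative-binomial screen simulator
    with planted ground truth for benchmarking every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    BiocGenerics,
    survival
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
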