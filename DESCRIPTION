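Package: sepalsig
Title: Hormone-Response Signature Scoring and Sepal Growth Coordination Metrics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Quantitative analysis toolkit for studying hormone-signaling
    differences and growth coordination in Arabidopsis flower buds. Implements
    per-cell and per-spot hormone-response gene-set transcript fractions with
    cluster-level genotype contrasts (Wilcoxon rank-sum, Bonferroni control),
    single-cell QC filters and cell-cycle variance-explained gene removal,
    spatial spot best-cluster assignment and proportion summaries, ratiometric
    reporter (BES1/H2B) per-sepal mean and CV quantification, and sepal
    growth-contribution and area-ratio metrics from live-imaging time series.
    Includes a synthetic-data generator with known ground truth that emulates
    every input the pipeline consumes, so all stages are testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment
Suggests:
    testthat (>= 3.0.0),
    scater,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
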