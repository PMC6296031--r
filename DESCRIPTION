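Package: gliadyn
Title: Longitudinal Microglia Transcriptome Analysis with Ensemble
    Co-Expression Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for longitudinal bulk RNA-seq analysis of
    microglia in a genotype-by-age factorial design. Implements exon-to-gene
    "rollup" summarization (exon filtering, robust two-way median-polish fit,
    median normalization), per-gene 2x4 factorial linear models with
    per-contrast Benjamini-Hochberg FDR and fold-change DEG calling,
    correlation-based temporal clustering of DEG trajectories, hypergeometric
    over-representation analysis and signed-regulon upstream-regulator
    activation z-scores, ensemble gene co-expression network inference (rank
    aggregation of multiple base methods with BIC neighborhood edge
    selection), consensus community detection with cell-type annotation, and
    cross-species module-overlap and connectivity statistics. Includes a
    synthetic-data generator with planted ground truth (negative-binomial
    exon counts under the factorial design, four temporal differential
    expression patterns, latent-factor co-expression modules) so every stage
    is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    glmnet,
    igraph,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
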