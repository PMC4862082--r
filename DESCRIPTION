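Package: recoex
Title: Replicability and Confound Diagnostics for Gene Co-Expression Networks
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds signed, weighted, rank-standardized gene co-expression
    networks from bulk and single-cell expression data under alternative
    data treatments (raw UMI counts, counts-per-million, binarized presence,
    zeroes-as-missing, pooled-across-groups), aggregates them
    meta-analytically, and quantifies how well network connectivity predicts
    gene function by neighbor-voting AUROC under cross-validation. Provides
    annotation-free topological replicability statistics (top-edge Jaccard
    overlap, semantic similarity of top connections, the standard deviation
    of aggregate connectivity against a permuted-network null) and
    diagnostics for expression-level confounds (node degree versus
    expression correlation, expression-matched control gene sets,
    high-expression gene filtering). Includes a seeded synthetic-data
    generator for batched UMI count matrices with planted co-expression
    modules, cell-type compositional shifts, batch effects, and
    expression-dependent drop-out, so every analysis can be exercised
    against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
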