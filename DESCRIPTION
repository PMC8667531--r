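Package: cider
Title: Meta-Clustering and Integration Evaluation for Multi-Batch
    Single-Cell RNA-Seq via Differential-Expression Similarity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies cell populations across batches of single-cell
    RNA-seq data by comparing groups of cells through their differential
    expression signatures rather than through cell-cell distances. For
    every pair of batch-specific initial clusters a per-gene linear model
    with group, batch, optional nested covariates and the scaled cellular
    detection rate is fitted; the Pearson correlation between the two
    group-versus-background coefficient vectors defines an inter-group
    similarity that is robust to additive batch effects. Similarities are
    assembled into a matrix, merged by complete-linkage hierarchical
    clustering into cross-batch populations, and explained gene-by-gene
    through leave-one-gene-out Fisher-z influence. The same similarity,
    combined with an empirical background distribution, evaluates
    integration results without ground truth by flagging falsely aligned
    clusters. A gamma-Poisson simulator with additive cluster, batch and
    covariate effects makes every stage testable, and adjusted Rand index
    and local inverse Simpson index helpers support benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    parallel,
    igraph,
    bluster,
    data.table,
    withr,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0),
    limma,
    mclust
Config/testthat/edition: 3
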