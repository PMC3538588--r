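Package: convergeR
Title: Genome-to-Phenome Convergence Analysis for Complex Disease
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for tracing the convergence of genome-wide association
    evidence onto disease pathways. Seed genes passing an association p-value
    cutoff are expanded one hop into a physical/genetic interaction network;
    the expanded set is screened against drug-gene (toxicogenomic) tables and
    per-tissue differential-expression calls made with the signed Diff-score
    convention; pathway enrichment (EASE / Fisher / hypergeometric with
    Benjamini-Hochberg or Bonferroni correction) of the per-condition
    intersection sets yields cross-condition common pathways, which are ranked
    by a leave-pathway-out ablation impact. A synthetic-data generator plants
    a convergent causal-pathway signal so every stage is exercisable and
    calibratable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
biocViews: Network, Pathways, GeneSetEnrichment, DifferentialExpression,
    GraphAndNetwork, SystemsBiology
RoxygenNote: 7.3.3
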