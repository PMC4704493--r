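Package: mimicscreen
Title: Analysis of Genome-Scale miRNA Mimic Toxicity Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for processing genome-scale gain-of-function miRNA mimic
    viability screens across cancer cell line panels: plate row-median
    normalization, replicate aggregation, z-score standardization and hit
    calling; hierarchical affinity-propagation clustering of phenotype
    profiles implemented from the message-passing update rules; seed-family
    variance decomposition with kernel density summaries; hypergeometric
    gene-set overlap, target context-score response curves and dual-pool
    siRNA phenocopy screening for functional target nomination;
    Kaplan-Meier/log-rank percentile cutoff-scan survival validation with
    train/validation splits; copy-number depth-ratio classification and
    top-variance gene filtering; and seeded synthetic-screen generators so
    the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
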