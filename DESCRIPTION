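Package: phylorep
Title: Phylogenetic Comparative Analysis of Gene Repertoire Evolution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Links gene-family copy-number evolution to regulatory domain
    architecture across a species phylogeny. Provides Dollo parsimony
    reconstruction of gain/loss histories for binary characters on a rooted
    tree, clade-wise enrichment and depletion testing of orthogroup counts
    (Fisher-Pitman permutation tests with Benjamini-Hochberg FDR control and
    a log-ratio Wilcoxon contrast), phylogenetic signal statistics
    (Blomberg's K and Pagel's lambda), phylogenetic generalized least
    squares under Brownian-motion covariance, canonical correspondence
    analysis with a permutation F test, a seeded synthetic-data generator
    that emulates clade-biased gene loss, and a deterministic pipeline
    driver producing machine-readable reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    nlme,
    phytools,
    picante,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
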