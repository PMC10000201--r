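Package: pathspec
Title: Pathway-Hierarchy Specificity Scoring and Enrichment for
    Seed-Protein Interactomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Links a seed regulator protein to tumor phenotypes through the
    network of pathway hierarchies. Parses Reactome-style pathway relation
    and annotation files into a directed hierarchy graph, decomposes it into
    source-rooted clusters, expands a two-layer protein-protein interaction
    neighborhood around a seed protein from PSI-MITAB records, maps three
    gene evidence sets (total annotation, differential expression hits,
    cancer genes reachable in the interactome) onto the hierarchy, ranks
    nodes by a specificity score, and tests hypergeometric enrichment or
    depletion of functional pathway sets and of hierarchy clusters within
    the high-score selection. Includes an exact two-tailed Fisher test for
    clinical contingency tables, the xenograft tumor-volume formula, and a
    synthetic-data generator with planted ground truth so every stage is
    testable without database downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
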