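Package: setora
Title: Classified Gene-Set Construction and Over-Representation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds classified gene-set collections for the major model
    organisms from ontology (OBO), annotation (GAF), expression (RPKM) and
    genotype-phenotype inputs, with direct and ancestor-propagated GO
    assembly, evidence-code subsets, GO-slim roll-up and a
    tissue-preferential expression classifier. Runs hypergeometric
    over-representation tests against these collections with configurable
    backgrounds, Bonferroni, Benjamini-Hochberg and Benjamini-Yekutieli
    adjustments, fold enrichment, shared-gene and uncovered-gene reports,
    multi-list comparison matrices and bipartite gene/gene-set network
    export. Includes deterministic synthetic-data generators for every
    input format and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
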