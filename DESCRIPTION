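Package: pleionet
Title: Network Contrasts Between Ageing-Related and Pleiotropic Disease Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A network framework for contrasting ageing-related genes with
    pleiotropic disease genes. Maps GWAS significant SNPs to genes, aggregates
    disease associations into disease clusters, and quantifies direct
    (pleiotropy) versus indirect (network-neighbour) association across
    protein-interaction, coexpression, and pathway network layers. Provides
    shortest- and average-path proximity transforms, random walk with restart
    on single layers and on a multiplex stack, intra- and inter-set
    coexpression coherence, the Tau tissue-specificity index, pathway-hierarchy
    positioning on directed acyclic graphs, size-matched gene-set permutation
    nulls, and balanced random-forest prediction of ageing-related genes under
    nested cross-validation. Includes a synthetic-study generator with planted
    signal so the full pipeline runs and is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    Matrix,
    GenomicRanges,
    IRanges,
    S4Vectors,
    ranger,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
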