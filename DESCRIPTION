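Package: syntrace
Title: Gene Family Delimitation, Microsynteny Sub-Lineages and Duplication Timing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs the evolutionary history of a gene family from
    multi-genome protein sets and gene order. Delimits the family by seeded
    traversal of an all-vs-all sequence-similarity network across an e-value
    sweep, scores conservation of the +/-15-gene chromosomal neighborhood
    around family members (microsynteny), partitions members into synteny
    sub-lineages, and evaluates duplication-timing scenarios on a species
    tree carrying a whole-genome-duplication (WGD) mark by counting implied
    gene losses under Dollo parsimony. Ships a genome-evolution simulator
    (speciation, WGD and ohnolog loss, tandem and dispersed duplication,
    translocation, gene loss, local gene-order shuffling) that provides
    ground-truth event logs for every pipeline stage, plus distance-based
    neighbor-joining trees with bootstrap support for orienting lineages.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    igraph,
    jsonlite,
    mclust,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
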