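Package: chordevo
Title: Comparative Genome Evolution Toolkit for Closely Related Species Pairs
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying how fast genomes evolve between closely
    related species pairs: double-cut-and-join (DCJ) rearrangement distances
    and rates on signed gene orders, genome aliquoting for post-duplication
    genomes, reciprocal-best-hit orthology and protein distances, intron
    phase statistics and shuffled-exon detection, protein domain-combination
    turnover under Dollo parsimony, conserved non-coding element (CNE)
    refinement, polymorphism and effective population size estimation, and
    transcription/methylation profiles by genomic region class. Includes a
    synthetic genome-evolution simulator with a ground-truth event log so
    that every estimator can be validated against planted events.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    igraph,
    IRanges,
    jsonlite,
    methods,
    S4Vectors,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
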