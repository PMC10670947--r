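Package: sineortho
Title: Orthologous SINE Insertion Loci from Assembled Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects copies of a SINE (short interspersed element) family in
    assembled genomes by iterative Smith-Waterman search with masking, finds
    pairwise orthologous SINE-containing loci by reciprocal mapping of
    300-bp left flanks, clusters and links candidate loci into
    double/multiple/poly groups, classifies each locus pair as plus-plus,
    plus-minus or minus-plus from a segmented triple alignment against the
    family consensus, resolves moderate multimapper clusters by
    closest-pair extraction, and joins pairwise verdicts across three or
    four genomes into phylogenetic presence/absence patterns. Ships a
    seeded genome simulator that plants truth-tabled insertions for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    igraph,
    ape,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
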