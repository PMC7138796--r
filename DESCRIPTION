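Package: stwintron
Title: Detection, Classification and Simulated Evolution of Spliceosomal
    Twin Introns
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Toolkit for the analysis of complex intervening sequences made
    of nested U2 spliceosomal introns ("stwintrons"). Provides consensus
    models of the three U2 splice elements (donor, lariat branch point,
    acceptor) with a two-tier canonicality scheme, exhaustive enumeration
    of candidate introns under length and spacing constraints, an
    intron-definition splicing engine that resolves ordered excision and
    enumerates alternative splicing paths, classification of nested intron
    pairs into the [D]/[L]/[A] stwintron taxonomy (sensu stricto and sensu
    lato), gene-model arithmetic (intron phases, mature mRNA assembly,
    intron-position conservation against a protein alignment), a seeded
    synthetic sequence generator that realizes nested-intron architectures
    with decoy splice motifs excluded, and a Monte-Carlo simulator of
    stwintron emergence by tandem donor duplication and point mutation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    jsonlite,
    methods,
    rtracklayer,
    S4Vectors,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
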