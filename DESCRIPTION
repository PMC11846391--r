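Package: satellitome
Title: Satellitome Discovery and Sex-Chromosome Satellite DNA Analysis from
    Unassembled Short Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for characterizing the satellite DNA complement (the
    "satellitome") of a genome directly from unassembled short reads, with an
    emphasis on comparing male, female and microdissected X/Y chromosome
    libraries.  Includes graph-based read clustering and tandem consensus
    monomer inference, iterative discovery with read subtraction, homology
    grouping into families and superfamilies, abundance estimation, Kimura
    2-parameter repeat landscapes, molecular dating of amplification events,
    minimum spanning tree haplotype networks, transposable-element association
    screens, genome-size apportionment arithmetic, and a fully specified
    synthetic-genome simulator with planted satellite families for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    igraph,
    jsonlite,
    methods,
    S4Vectors,
    stats,
    utils
Suggests:
    ape,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
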