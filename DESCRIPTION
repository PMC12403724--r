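Package: stwintronr
Title: Detection and Analysis of [D1,2] Spliceosomal Twin Introns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting and analysing [D1,2] spliceosomal twin
    introns (stwintrons) in fungal genomic sequence. A stwintron is a pair
    of nested U2 introns in which an internal intron interrupts the 5'
    donor of an external intron between its first (G) and second
    nucleotide, so the internal intron must be excised before the external
    intron's splice sites are reconstituted. The package implements an
    explicit nested-intron grammar over IUPAC splice-site consensus motifs
    (GURWGY/GCRWGY donors, RYURAY branch element, HAG acceptor),
    enumerates splice products (pre-mRNA, splinter intermediate, mature
    mRNA, and the single-excision misspliced product that retains one
    intronic G), discovers near-terminal inverted repeat elements
    (NTIRE-9/10) under Watson-Crick plus GU-wobble pairing, scores
    terminal symmetry by aligning an intron against its own reverse
    complement, checks integration-site properties (target-site
    duplication, flanking dinucleotide bias), classifies junction-spanning
    reads, clusters sequence-similar sister stwintrons, and generates
    fully ground-truthed synthetic genomes and read sets for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    ape,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
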