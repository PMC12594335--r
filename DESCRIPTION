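Package: miRvet
Title: Structural and Expression-Based Validation of MIRNA Annotations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Validates candidate MIRNA locus annotations against small
    RNA-seq evidence without requiring a reference genome. Each candidate
    hairpin precursor is folded to its minimum-free-energy secondary
    structure, the mature miRNA (and miRNA*, supplied or predicted) is
    indexed on the hairpin, and the locus is scored against structural
    criteria (a single miRNA/miRNA* duplex with two-nucleotide 3'
    overhangs, bounded mismatches and asymmetric bulges, duplex-strand
    length limits) and expression criteria (a per-library read floor and
    a precision threshold computed from perfectly aligned forward-strand
    reads with one-nucleotide positional variance). Failed loci can
    optionally be rescued by re-evaluating the most abundant aligned
    20-24 nt sequence as an alternative mature miRNA. Includes a
    synthetic-fixture generator with planted, verified duplex geometry
    for testing every criterion end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    tools,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
SystemRequirements: ViennaRNA (RNAfold on the PATH)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
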