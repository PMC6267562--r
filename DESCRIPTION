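Package: crisprCanvas
Title: Comparison and Publication-Ready Visualization of CRISPR Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Compares CRISPR spacer content across bacterial isolates and
    draws presentation-ready SVG figures. Spacers are extracted from
    CRISPRDetect-style GFF3 output (or a spacer FASTA), aligned pairwise with
    a built-in Smith-Waterman aligner, scored by an adjusted nucleotide
    mismatch count that penalizes unaligned query overhang, clustered by
    transitive closure at a user-set mismatch cutoff, and assigned stable
    two-color hexadecimal codes per cluster. Strains are ordered by
    Bray-Curtis dissimilarity of shared spacer content with UPGMA guide-tree
    leaf ordering, or by a custom list. Display options include graying out
    unique or shared spacers, spacer-length overlays, and persistent color
    stores so appended datasets keep their colors. A seeded fixture generator
    emulating CRISPRDetect output supports fully offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    ape
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2,
    vegan,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
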