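Package: aluscan
Title: Discovery of Expressed Alu-Containing lncRNA Candidates in Immune Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for mining expressed Alu-containing long non-coding RNA
    candidates inside immune genes from bulk RNA-seq alignments. Builds an Alu
    element catalog from a RepeatMasker-derived track, derives intron/UTR
    features from Ensembl-style gene annotation, intersects repeats with gene
    bodies under a minimum-overlap fraction, classifies each insertion's
    position and orientation, links CAGE-derived transcription start sites,
    counts aligned fragments per insertion, normalises by median-of-ratios size
    factors, applies an expression and fold-change filter cascade with Welch
    t-tests and Benjamini-Hochberg correction, and assembles a candidate table
    with summary tallies. A synthetic-fixture generator produces toy genomes,
    repeat and TSS tracks, alignments and negative-binomial count matrices with
    known ground truth so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    GenomicAlignments,
    Rsamtools,
    rtracklayer,
    ape,
    jsonlite,
    yaml,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
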