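Package: dotvntr
Title: Dot-Plot Discovery of Coding-Region Tandem-Repeat Polymorphism
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Genome-wide discovery of variable-number tandem repeats (VNTRs)
    in protein-coding sequences by dot-plot self- and cross-alignment
    geometry. Extracts and pairs orthologous coding sequences from genome
    assemblies (FASTA + GFF3), computes ungapped seed-and-extend anchor
    segments between alleles, detects tandem-repeat signal blocks from
    families of parallel dot-plot diagonals, estimates repeat unit length
    and per-allele copy number, and flags copy-number polymorphism through
    the block height/width ratio. Includes repeat-unit decomposition with
    GC content and nucleotide diversity (pi), a hierarchical
    haplotype-painting procedure for MHC-like loci based on per-window SNP
    density, and a seeded synthetic-data generator with machine-readable
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
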