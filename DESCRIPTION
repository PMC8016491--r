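Package: contigsv
Title: Structural Variant Detection and Genotyping from Genome Assembly
    Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects and genotypes six classes of structural variants
    (insertions, deletions, inversions, tandem and interspersed
    duplications, and translocation breakends) from alignments of haploid
    or haplotype-resolved diploid genome assemblies against a reference
    genome. Variant signatures are collected per haplotype from long
    alignment gaps (CIGAR insertions and deletions) and from discordant
    split-alignment segments, paired across haplotypes by the Levenshtein
    distance of their variant sequences, genotyped by the pairing outcome,
    and written to VCF including reciprocal breakend records. A synthetic
    genome module generates reference sequences, haplotypes with implanted
    variants of controlled zygosity, and the corresponding ideal SAM
    alignments for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicAlignments,
    Rsamtools,
    methods,
    stats,
    utils
Suggests:
    BiocGenerics,
    GenomicRanges,
    VariantAnnotation,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
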