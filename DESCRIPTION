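Package: hybridscope
Title: Parent-of-Origin Analysis of Hybrid Transcriptomes from
    Dual-Reference Alignments and Trio Variant Calls
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for dissecting the transcriptome of an interspecies
    hybrid sequenced together with both parents. Reads aligned
    competitively against the two parental reference genomes are
    arbitrated read-by-read with a hierarchical CIGAR score (matching
    bases, then indel events, then clipped bases); the resulting
    parent-specific read partitions feed an FPKM-based transcriptome
    comparison (expression filters, top-N overlaps, four-set
    intersections, reference-set cross-references). Trio variant calls
    with allelic depths are filtered to sites where the parents are
    alternatively homozygous, classified by hybrid zygosity, binned by
    signed allelic-depth ratio, and summarized into parental-origin
    blocks along the genome; parent-of-origin calls are cross-referenced
    against an imprinting database. A synthetic-data module simulates
    two diverged parental genomes, hybrid reads, alignments and trio
    variant calls with known ground truth so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rsamtools,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
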