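Package: eprinttools
Title: Differential RNA-Binding-Protein Activity from Exonuclease-Assisted
    Protein-RNA Footprint Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Downstream analysis of exonuclease-assisted protein-RNA
    interaction profiling (ePRINT) experiments: replicate peak merging and
    the high-confidence filtering cascade against size-matched input
    libraries, negative-binomial differential binding with host-gene
    expression entering as per-peak offsets, gene-feature classification of
    peaks, position-weight-matrix motif scanning with positional z-profiles,
    directional peak-set enrichment (preranked GSEA), CLIP-proximity overlap
    and layered RBP regulatory network construction, unbiased 6-mer
    clustering, and a seeded synthetic-experiment generator with ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2,
    fgsea,
    mclust
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
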