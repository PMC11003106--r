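Package: scifiatac
Title: Barcode Demultiplexing, Collision Modelling and QC for
    Combinatorial Fluidic Indexing Single-Cell ATAC-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computational toolkit for droplet single-cell ATAC-seq with
    plate-based Tn5 pre-indexing (combinatorial fluidic indexing).
    Provides a synthetic-experiment generator with full ground truth;
    construction and error-correction of combined bead + two-sided Tn5
    cell barcodes; conversion of aligned fragments to single-base Tn5
    insertion sites with per-nucleus quality control (TSS fraction,
    FRiP, organelle fraction); a binomial/Bayes genotype model that
    detects cell-barcode collisions and quantifies index-hopping
    contamination from allele counts at homozygous biallelic SNPs; an
    analytic droplet-occupancy ("birthday problem") model of same-well
    barcode collision rates with a same-genotype correction; and
    pseudobulk chromatin-accessibility scoring (gene scores, CPM,
    Z-scores, ACR master lists, specificity calls, library
    correlation).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    edgeR,
    rtracklayer,
    VariantAnnotation,
    SummarizedExperiment,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
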