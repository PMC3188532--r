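Package: tarscribe
Title: Transcriptionally Active Region Discovery and Digital Expression
    Analysis for RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Post-alignment transcriptome analysis for bulk RNA-seq and
    small-RNA sequencing. Detects transcriptionally active regions (TARs)
    from per-base read coverage, assembles paired-end-linked novel
    transcript units in intergenic space and clusters them into regions,
    validates splice junctions and classifies alternative-splicing events
    (alternative 5'/3' splice site, exon skipping, intron retention),
    detects read-supported extensions of annotated gene boundaries,
    performs two-library differential expression with the Audic-Claverie
    exact test (RPKM normalisation, Benjamini-Hochberg FDR) and
    hypergeometric GO enrichment, processes small-RNA tag tables (length
    filtering, annotation cascade, known-miRNA matching with mismatch
    tolerance, TPM), and joins differentially expressed genes to GWAS hits
    within a genomic window. Includes a seeded synthetic-data generator
    with machine-readable planted truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    igraph,
    jsonlite,
    rtracklayer,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
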