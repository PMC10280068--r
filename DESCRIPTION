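Package: ighap
Title: Amplicon Haplotype Analysis of Intraorganismal Genetic Heterogeneity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Calls haplotypes from deep amplicon sequencing of a single locus
    to characterise intraorganismal genetic heterogeneity (somatic mosaicism):
    quality trimming, exact primer matching, dereplication, de novo two-parent
    chimera removal, abundance-thresholded haplotype calling for bulk tissue and
    single-cell libraries, reference-anchored alignment, neighbor-joining
    grouping, transition/transversion SNP classification with exon/intron
    partitioning and per-kilobase densities, and codon-level synonymous versus
    nonsynonymous impact with haplotype collapse from genomic DNA to spliced
    exons to protein. Includes a mosaic-population amplicon read simulator with
    a machine-readable truth table for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    ape,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
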