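Package: stclust
Title: Stepwise Threshold Clustering for Multi-Locus Amplicon Genotyping
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: De-novo genotyping of multigene-family amplicons (such as MHC
    class II beta exon 2) from next-generation sequencing reads. Reads are
    demultiplexed by dual barcodes and length-filtered; length-variant
    sequencing artifacts (mostly homopolymer indels) are combined back into
    their source sequences; reads are then clustered at stepwise increasing
    similarity thresholds and clusters - rather than individual sequences -
    are classified as alleles or artifacts by size and dominance criteria;
    finally, small clusters are rescued by cross-checking across samples and
    candidate alleles are screened for PCR chimeras. Includes a synthetic
    amplicon-read simulator with ground truth for validating genotype
    recovery, and amplification-efficiency diagnostics.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    Rcpp,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
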