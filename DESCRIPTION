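Package: aptseq
Title: Joint Aptamer and Transcriptome Deconvolution for Droplet
    Single-Cell Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Deconvolutes polyadenylated aptamer surface tags and mRNA from
    droplet-barcoded paired-end single-cell sequencing reads.  Provides
    barcode and UMI extraction with abundance-based cell calling,
    mismatch-tolerant 20-mer demultiplexing of an aptamer panel, a minimal
    k-mer pseudoaligner that counts UMIs per transcript equivalence class,
    species-mixing (barnyard) coordinates, SVD-based decomposition of the
    cell-by-aptamer matrix with a two-channel colour mapping, and qPCR
    standard-curve fitting with uncertainty propagation.  A synthetic-data
    generator emits reads and qPCR traces with known ground truth so every
    stage is verifiable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    data.table,
    Matrix,
    Rcpp,
    methods,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
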