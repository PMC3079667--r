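Package: ampliSNP
Title: Amplicon-Based Mitochondrial SNP Discovery with Combinatorial
    Dual-Barcode Demultiplexing
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for SNP discovery in pooled amplicon
    pyrosequencing experiments, modelled on combinatorial dual-MID
    (multiplex identifier) tagging of PCR amplicons over a mitochondrial
    reference. Provides error-correcting decoding of 10-bp barcodes at
    both read ends, primer-based amplicon routing, semi-global alignment
    of inserts to reference amplicons, strand-resolved per-individual
    pileups, and a stringent multi-criterion variant-validation cascade
    that rejects pyrosequencing artifacts (homopolymer under-reads and
    carry-forward insertions), requires double-strand support, a 90
    percent replicate-read majority with read-count thresholds and
    cross-sample rescue, and observation in more than one individual.
    Includes a read simulator with ground-truth provenance, per-region
    panel statistics, population-sharing summaries, and VCF output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    data.table,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    jsonlite,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
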