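Package: tecascade
Title: Detecting, Dating and Tracing Transposable Element Invasions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying recent transposable element (TE) invasions
    across species from sequencing data. Implements coverage-normalised TE
    copy-number estimation from short reads with a built-in seed-and-extend
    mapper, TE-internal SNP calling from consensus pileups, a Smith-Waterman
    scanner for locating TE insertions in genome assemblies together with
    length/divergence filters, a cross-assembly similarity statistic,
    full-length (two-LTR) classification, piRNA-cluster (trap model)
    accounting, piRNA ping-pong and strand-bias profiling, and rule-based
    reconstruction of invasion windows and horizontal-transfer cascades from
    multi-strain time series. A synthetic-data module generates genomes with
    planted insertions, error-bearing short reads, piRNA pools and
    multi-species cohorts with known ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rcpp,
    Rsamtools,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
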