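Package: crossExpress
Title: Cross-Platform Integration of Open- and Closed-Platform Gene
    Expression Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Combines gene-expression measurements from open platforms
    (sequencing reads, SAGE/MPSS tags) and closed platforms (microarray
    probes) into a single target-by-sample table. Tags are matched to a
    user-defined target reference (identifiers of the form superID@subID)
    by genomic position with a sweep-line interval join, annotated
    against user-defined exclusion features (e.g. SNP positions, the
    derived multiTarget cross-hybridization set), filtered, and
    summarized per platform with Tukey median polish (closed) or RPKM
    (open). Includes scalable column binding and quantile normalization
    of per-sample probe tables, bedGraph coverage-track export,
    evaluation utilities (gene coverage, correspondence-at-the-top
    curves, correlation matrices), and a seed-reproducible synthetic
    fixture generator with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
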