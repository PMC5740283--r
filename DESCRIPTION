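Package: hzfootprint
Title: Detecting Genomic Footprints of Hybrid Zone Movement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for testing whether an enclave of one species inside the
    range of a parapatric congener arose by incomplete species replacement.
    Implements the full inference chain used in hybrid zone studies of
    co-dominant nuclear markers: Bayesian admixture clustering with Evanno
    delta-k model choice, diagnostic-marker discovery and hybrid indices,
    heterozygosity-ancestry triangle statistics, Thiessen-polygon spatial
    analysis with 0.5-contour transects, geographic cline fitting with
    exponential tails and AICc model selection, and Fisher / Mann-Whitney
    tests for asymmetric introgression. Includes a synthetic-data generator
    for stable versus moving contact-zone scenarios so every stage can be
    validated against a known generating field.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    Rcpp,
    ape,
    deldir,
    interp,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
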