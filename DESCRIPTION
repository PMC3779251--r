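Package: riboprobe
Title: Organism-Specific Ribosomal RNA Depletion Probe Design
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Designs capture probes for ribosomal RNA depletion that are
    specific to a single organism. Target rRNA genes are virtually fragmented
    into overlapping windows, each window is screened by local alignment
    against every coding sequence of the same genome, and windows with the
    smallest number of qualifying similarity hits (E-value, identity and
    coverage thresholds) are selected as probes. Includes inverted-repeat
    hairpin screening of candidate probes, a deterministic synthetic-genome
    simulator with planted homology for validation, and a comparative-Ct
    (2^-ddCt) calculator for qPCR-based depletion evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    rtracklayer,
    GenomicRanges,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    stringr,
    ggplot2,
    generics,
    jsonlite,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
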