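Package: g4kit
Title: Analysis Toolkit for G-Quadruplex CUT&Tag Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for the computational analysis of G-quadruplex (G4)
    CUT&Tag experiments: putative G-quadruplex sequence (PQS) scanning for
    canonical, extended-loop, two-tetrad and inter-strand motif classes;
    peak-set ranking, replicate consensus, overlap partitioning with
    randomization significance and chromatin-state annotation; coverage
    tracks with RPGC (1x genome coverage) normalization, FriP, fingerprint
    curves and telomeric repeat content; exogenous spike-in (qCUT&Tag)
    scale factors; and a synthetic-data generator producing genomes with
    implanted PQS truth sites and enrichment-structured fragment libraries
    so the whole pipeline is testable without external downloads. All
    user-facing functions take data frames and return tibbles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    methods,
    purrr,
    rlang,
    Rsamtools,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
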