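Package: rcnoise
Title: Resource Competition and Gene Expression Noise in Two-Reporter Circuits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stochastic analysis of how competition for shared transcriptional
    and translational resources shapes gene expression noise in a two-reporter
    synthetic circuit. Builds birth-death reaction networks for unlimited,
    competitive, orthogonal and frozen-cross resource modes; simulates them
    exactly with the Gillespie direct method; solves the truncated chemical
    master equation for stationary joint distributions; and derives the
    fluctuation-dissipation (linear noise) decomposition of protein noise into
    intrinsic birth/death, own-mRNA and resource-competitive components.
    Includes a family of negative-feedback noise controllers (negatively
    competitive regulation, local, and global) in four placements along the
    protein biosynthesis pathway, with grid experiments and summary metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    Matrix,
    deSolve,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
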