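Package: pathact
Title: Bayesian Network Inference of Signal Transduction Pathway Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the functional activity of signal transduction
    pathways (androgen receptor, Hedgehog, TGF-beta, NF-kB, Wnt, ER,
    PI3K-FOXO and similar) in individual expression samples. A
    tree-structured Bayesian network links a latent transcription complex
    to its direct target genes and to the microarray probesets measuring
    them; exact inference yields the probability that the pathway is
    active, reported as a log2odds activity score. Includes calibration of
    probeset conditional probabilities on ground-truth labeled samples,
    model freezing and per-tissue threshold recalibration, the
    FOXO/SOD2 oxidative-stress interpretation rule for the PI3K pathway,
    matrix-level microarray quality control, a generative simulator for
    synthetic calibration data, and rank-based group comparison and
    correlation statistics, with readers for TSV expression matrices and
    GEO series-matrix files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
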