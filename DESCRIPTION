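Package: shapeseqr
Title: Decay-Corrected Reactivity Estimation for SHAPE-Seq RNA Structure Probing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A complete computational pipeline for two-channel RNA chemical
    probing experiments read out by sequencing (SHAPE-Seq style): demultiplexing
    of paired-end reads by degenerate channel handles, adapter trimming,
    fragment alignment and reverse-transcriptase (RT) stop counting, maximum-
    likelihood correction of natural RT drop-off to obtain per-nucleotide
    modification probabilities (theta), length-rescaled reactivities (rho),
    pseudo-free-energy folding constraint files, and sensitivity/PPV scoring of
    predicted secondary structures. Includes a generative simulator of the
    two-channel RT-stop process, from ground-truth parameters down to paired
    FASTQ files, so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    knitr,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
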