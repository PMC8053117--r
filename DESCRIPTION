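Package: cas9profiler
Title: In Vitro Cas9 Cleavage Specificity Profiling from Doped Target Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for in vitro CRISPR-Cas9 specificity profiling
    with partially randomized (doped) plasmid target libraries. Covers doped
    library design statistics (binomial mismatch distributions and
    mismatch-combination counting), quantification of supercoiled, nicked and
    linearized plasmid pools from gel band intensities with one-phase
    association rate fitting, extraction and mismatch annotation of target
    sequences from amplicon sequencing reads, mismatch-stratified estimated
    and relative abundance analysis with on/off-target specificity scores,
    position-by-nucleotide bubble-heatmap statistics, and two-mismatch spacing
    analysis. A synthetic-data generator simulates doped libraries evolving
    under sequential first-order nick-then-linearize cleavage kinetics and
    emits FASTQ pools, gel-lane intensities and ground-truth tables so the
    whole pipeline is testable without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    deSolve,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
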