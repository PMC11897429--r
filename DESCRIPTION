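Package: scnanosim
Title: Simulation of Single-Cell Nanopore Long-Read Sequencing Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Generates synthetic single-cell Oxford Nanopore long-read
    datasets with full ground truth. Starting from a feature-by-cell UMI
    count matrix (real or simulated via a Gamma-Poisson model with
    log-normal library sizes) and a reference transcriptome, the package
    assembles "perfect" cDNA library molecules with the 10x/Nanopore read
    structure (adapter, cell barcode, UMI, oligo-dT, cDNA, TSO), applies
    length-biased transcript choice, optional intron retention and
    empirically estimated cDNA truncation, simulates PCR amplification
    bias as a branching process with heritable copy errors, and injects
    Nanopore-like sequencing errors driven by a beta-distributed read
    identity model, writing FASTQ with per-base quality scores plus a
    quality-control report. All stages are importable functions returning
    tibbles; a thin command-line wrapper chains them into a pipeline.
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
    graphics,
    jsonlite,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    fitdistrplus,
    GenomicRanges,
    optparse,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
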