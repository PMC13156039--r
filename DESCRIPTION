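Package: ligrec
Title: Ligand-Receptor Interactome Analysis for Time-Course Single-Cell RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers cell-cell communication from time-course single-cell
    RNA-seq of neuro-immune tissue. Implements quality-control and
    cell-selection rules, per-cell-type Wilcoxon differential expression
    with Benjamini-Hochberg correction, a stratified-background
    ligand-receptor activity score with zero-clipping and replicate
    averaging, gene-module scoring scaled to the unit interval, a
    label-permutation test, and cell-type composition fold-change
    analysis. Ships a negative-binomial single-cell count simulator with
    planted communication programs so the whole pipeline is testable
    end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
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
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
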