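Package: mtctt
Title: Microtubule Lattice Models and Alpha-Tubulin C-Terminal Tail
    Accessibility Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds 13-protofilament microtubule lattice models from a tubulin
    dimer template by helical-symmetry rigid-body replication, grafts the
    disordered alpha-tubulin C-terminal tail (alphaCTT) onto every alpha
    subunit, and analyses trajectories of the tails for salt bridges with four
    basic-residue interaction sites on the tubulin body. Reduces contact
    records to per-residue interaction-rate matrices and the per-frame
    fraction of tails that are inaccessible (bound to the lattice). Includes
    a seeded coarse-grained Metropolis Monte Carlo simulator of tethered tail
    bead chains with site-specific attractive wells encoding the GDP versus
    GTP lattice contrast, used to generate synthetic trajectories in the
    formats the contact analysis reads. Tabular results are tibbles designed
    for pipe-based workflows, with ggplot2 autoplot methods and broom-style
    tidiers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
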