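Package: cellframe
Title: Tidy Tabular Abstraction over Single-Cell Expression Containers
Version: 0.1.0
Authors@R:
    person("cellframe", "developers", email = "cellframe@example.org",
           role = c("aut", "cre"))
Description: Presents a hierarchical single-cell expression container
    (sparse assays, cell metadata, dimensionality reductions) as a single
    tidy table with one row per cell, and adapts the grammar-of-data verbs
    (mutate, filter, select, joins, nesting and friends) to operate on it.
    Verbs return a container-backed view whenever the operation neither
    duplicates cells nor breaks the cell-identifier key column, and demote
    the result to a plain tibble otherwise. Includes transcript-abundance
    joining, per-group nested analysis, quality-control metrics, library-size
    log-normalization, multi-gene signature scoring, variance-ranked variable
    features, a deterministic PCA embedding, polygon gating, MatrixMarket
    (10x-style) input/output, a negative-binomial synthetic PBMC-like data
    generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    rlang,
    tibble,
    dplyr,
    tidyr,
    stats,
    utils,
    grDevices,
    withr,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
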