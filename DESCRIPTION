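Package: scbundle
Title: Build and Query Static Single-Cell Visualization Bundles
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compiles single-cell expression matrices, cell metadata and 2D
    embedding coordinates into self-contained static dataset bundles with
    per-gene random access, and reproduces the interactive operations of a
    single-cell browser as deterministic, headless functions: coloring by
    metadata or gene expression, metadata filtering and cell export, violin
    comparisons against background cells, cluster-by-gene heatmaps, and
    ATAC peak-near-gene queries. Importers cover MatrixMarket (MTX),
    dense TSV/CSV, AnnData h5ad and Loom. Bundles are plain static files
    that any web server (or the local filesystem) can serve; no compute
    backend is required. Includes a seeded synthetic-data generator with
    known cluster structure, headless SVG/PNG renderers with
    machine-readable render reports, hierarchical dataset collections, and
    an 'scb' command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    data.table,
    jsonlite,
    rhdf5,
    digest,
    stats,
    utils,
    grDevices,
    graphics,
    methods,
    tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
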