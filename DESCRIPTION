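Package: atlasmap
Title: Compressed Single-Cell Reference Atlases and Query Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds integrated low-dimensional references from single-cell
    gene expression (or chromatin accessibility) count matrices, compresses
    them into a minimal set of mappable elements whose size is independent of
    the number of reference cells, and places new query cells into the frozen
    reference embedding while removing query batch effects with a per-cluster
    ridge-penalized mixture-of-experts model. Includes k-nearest-neighbor
    transfer of discrete labels and continuous annotations, Mahalanobis-based
    mapping confidence scores for novel cell-state detection, and
    embedding-fidelity metrics (neighborhood distance correlation, local
    inverse Simpson index, per-type F1). Ships a deterministic synthetic-data
    generator with known cluster structure and batch effects, plus a
    command-line interface over MatrixMarket/TSV inputs and HDF5 reference
    containers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    irlba,
    RANN,
    rhdf5,
    jsonlite,
    methods,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    class,
    cluster
Config/testthat/edition: 3
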