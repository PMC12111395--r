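Package: rsspca
Title: Robust Sparse Smooth Principal Component Analysis for Image Stacks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Robust principal component analysis for stacks of equally sized
    grayscale images, combining an L1-norm objective (robustness to occlusions
    and gross outliers), an L1 sparsity constraint (feature selection), and a
    graph-Laplacian smoothness constraint encoding the two-dimensional pixel
    lattice. Components are extracted one at a time by a
    Minorization-Maximization iteration with deflation. Includes the classical
    L2 eigendecomposition baseline, PCA-L1, and both published RSPCA update
    rules as special cases; evaluation protocols for occlusion-robust
    reconstruction and nearest-neighbour recognition; a synthetic image-stack
    generator with planted sparse smooth components; and a small command-line
    interface with eigenface-style component rendering.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    png
Config/testthat/edition: 3
RoxygenNote: 7.3.3
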