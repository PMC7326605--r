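Package: meshops
Title: Automated Manipulation of Labeled Tetrahedral and Triangle Meshes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scriptable operations on labeled tetrahedral and triangular
    meshes as they arise in image-based anatomical modeling pipelines:
    boundary and interface surface extraction by set algebra on region
    labels, manifold-aware shrinkage-free (Taubin) smoothing of coordinates
    and data fields with element-quality guards, mesh re-sampling by
    iterative edge bisection and quality-guarded edge collapse, submesh
    extraction and re-insertion with invertible index mappings,
    proximity-based overlap extraction and mesh merging with vertex
    unification.  Reads and writes the CARP plain-text multi-file mesh
    dialect (.pts/.elem/.lon/.surf/.vtx/.dat/.vec) and VTK legacy ASCII
    unstructured grids, and ships deterministic generators of labeled
    synthetic meshes for testing.  A mode-based command-line front end is
    provided in inst/exec.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    Matrix,
    stats,
    utils
Suggests:
    jsonlite,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
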