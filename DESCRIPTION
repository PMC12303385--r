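Package: venanet
Title: Hydrodynamic Modeling of Full-Scale Leaf Venation Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modeling fluid transport through complete leaf venation
    networks at the level of individual veins. Extracts venation graphs from
    binary vein-segmentation masks (skeletonization, node detection, edge
    tracing with widths, pruning, and boundary-clipped Voronoi drainage
    areas), solves Kirchhoff flow on the weighted graph Laplacian with an
    ensemble of area-weighted fluctuating sinks, optimizes edge
    conductivities by fixed-point iteration under a material-cost constraint
    (with k-means subsystem decomposition for large networks), fits the sink
    fluctuation amplitude by edge-to-edge width comparison, and evaluates an
    extended Murray's law for reticulate networks with a fitted branching
    exponent. Includes a synthetic leaf-lattice generator for validation and
    parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    stats,
    utils,
    grDevices,
    EBImage,
    png,
    deldir,
    spatstat.geom
Suggests:
    testthat (>= 3.0.0),
    MASS,
    optparse,
    tiff
Config/testthat/edition: 3
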