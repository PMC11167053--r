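Package: cellpatch
Title: Patch-Based Segmentation Orchestration and Spatial Analysis for
    Image-Based Spatial Omics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Technology-invariant building blocks for image-based spatial
    omics (spatial transcriptomics and multiplex imaging): overlapping
    patch grids with pluggable per-patch segmentation, merging of
    duplicated cell boundaries by intersection-over-min-area, chunked
    per-cell channel averaging and partitioned transcript counting,
    staining-based cell-type annotation, hop-distance statistics between
    cell categories on a pruned Delaunay graph, polygonization of spatial
    niches with geometry statistics, and export to an open pyramidal
    visualizer bundle. Includes a deterministic synthetic-tissue
    generator so the full pipeline runs end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    polyclip,
    deldir,
    sp,
    EBImage,
    Matrix,
    methods,
    jsonlite,
    yaml,
    tiff,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
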