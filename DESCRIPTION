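Package: physis
Title: Quantification of Growth-Plate Bridging and Image-Based Finite-Element
    Modeling from MicroCT Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify bony bridging across the epiphyseal growth
    plate in 3D microCT images of long bones. Provides volume input/output
    with physical voxel metadata (TIFF stacks, NRRD, MetaImage, raw+JSON),
    3D median filtering, rigid alignment to the shaft axis, seed-based
    region-growing segmentation, detection of mineralized bridges spanning
    the growth plate with a minimum-volume filter and skeleton-based center
    extraction, projection of bridge centers onto the tibial joint surface,
    windowed areal number-density maps, a synthetic phantom generator with
    exact ground truth, and a voxel-based linear tetrahedral finite-element
    model (isotropic linear elasticity, von Mises post-processing,
    mesh-sensitivity selection) for simulating static compressive loading.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    methods,
    tibble,
    generics,
    jsonlite,
    tiff,
    png,
    yaml,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
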