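Package: ctfiber
Title: Collagenous Connective Tissue Architecture Mapping in 3D Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Characterises the three-dimensional architecture of
    collagen-containing connective tissue in colour cryo-section image
    stacks. Provides colour-based segmentation of collagenous structures,
    isometric summative binning, directional minimum-thickness fields by
    bidirectional ray casting, per-voxel orientation tensors built from
    dyadic sums of scan-ray vectors with Westin linear/planar/spherical
    anisotropy measures and structural classification, per-anatomical-region
    statistics, depth-coded X-ray projections, and synthetic tissue phantoms
    for end-to-end validation. All volumes are read and written as
    compressed NIFTI-1, including RGB and symmetric-matrix encodings.
License: MIT
Encoding: UTF-8
Imports:
    RNifti,
    EBImage,
    Rcpp,
    png,
    yaml,
    grDevices,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
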