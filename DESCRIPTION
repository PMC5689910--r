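Package: voxray
Title: Ray-Cast Fusion of 4D Multimodal Radiotherapy Volumes and Contour
    Quality Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A software ray-caster for fused visualization of mixed-resolution
    3D/4D PET/CT image volumes, delineation iso-surfaces and iso-dose surfaces
    in one unified world coordinate system, with region-of-interest clipping,
    delineation-based masking, surface point picking and margin-volume
    intersection highlighting. Includes the quantitative contour-assessment
    layer used in radiotherapy planning quality assurance: rasterization of
    planar structure-set contours to binary volumes, majority-vote internal
    target volume (ITV) construction, Dice and average/maximum/95% Hausdorff
    surface distances, inter-rater conformity, acceptance decisions, and
    cumulative dose-volume histograms. A seeded synthetic 4D breathing phantom
    emulating a multi-source planning layout (full-body CT, 4D-CT, 4D-PET,
    planning CT, delineations, dose) makes the whole pipeline testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    png,
    tibble,
    ggplot2,
    stats,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr
Config/testthat/edition: 3
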