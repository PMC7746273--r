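Package: layerglm
Title: Layer-Specific fMRI Analysis by Equivolume Layering and Spatial GLM Unmixing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for laminar (cortical depth resolved) functional MRI analysis:
    signed-distance level sets and equivolume intermediate surfaces between the
    white-matter and pial boundaries, per-voxel layer volume distributions, spatial
    general linear model unmixing of partial-volume BOLD signals into compartment
    time courses, boundary-based registration of cortical surfaces to functional
    volumes including the recursive (partition-wise) variant, orientation-preference
    voxel selection from a functional localizer, temporal GLM response estimation
    with canonical HRF and high-pass filtering, and repeated-measures group
    inference.  A synthetic cortical phantom and forward BOLD simulator with known
    laminar ground truth make every stage verifiable without scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    RNifti,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
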