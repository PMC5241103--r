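Package: smrirt
Title: Spectroscopic MRI-Guided Radiotherapy Target Planning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for integrating whole-brain spectroscopic MRI (sMRI)
    metabolite maps into glioblastoma radiotherapy target planning.
    Implements grid-aware 3D volume and mask handling with NIfTI input and
    output, planar-contour structure sets, trilinear resampling between the
    coarse spectroscopic grid and the clinical planning grid, contralateral
    normal-appearing white matter fold-normalization of Cho/NAA ratio maps,
    threshold segmentation of metabolic abnormalities, margin-based target
    volume construction using exact anisotropic Euclidean distance
    transforms, a parametric conformal dose surrogate, volumetric, spatial,
    dosimetric and recurrence-coverage metrics, cohort-level statistical
    tests, and a synthetic brain-tumor phantom generator providing ground
    truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    tibble,
    dplyr,
    purrr,
    ggplot2,
    generics,
    jsonlite,
    stats,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
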