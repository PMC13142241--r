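Package: extravas
Title: Quantifying Immune-Cell Extravasation in Cleared 3D Tumor Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures how far adoptively transferred immune cells escape from
    the tumor vasculature in multi-channel 3D fluorescence volumes of optically
    cleared tumors. Provides vessel and cell segmentation, anisotropic
    Euclidean distance-to-vessel mapping, nucleus spot detection,
    intravascular/extravascular voxel masking, and the derived endpoints
    (extravasation volume fraction, extravasated-cell counts, escape distance
    at a cumulative quantile, and the CPDmax/CPD50/CPA50 and CDDmax/CDD50/CDA50
    penetration and cytotoxicity depth metrics), together with a synthetic
    cleared-tumor volume generator with exact ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    tiff,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
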