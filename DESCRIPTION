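Package: auriMorph
Title: 3D Morphometry and Measurement-Quality Statistics for Ear Cartilage Segmentations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantitative assessment of patient-specific ear (auricular)
    cartilage shape from 3D segmentation masks. Computes cartilage volume,
    surface area (triangulated 0.5-level isosurface) and model-independent
    mean thickness (maximal inscribed spheres over a Euclidean distance
    transform) on anisotropic voxel grids; reproduces a micro-CT reference
    segmentation chain (truncated Gaussian filtering plus dual attenuation
    thresholding); and quantifies segmentation precision (Glüer precision
    errors, two-way absolute-agreement single-measure intraclass
    correlation, pairwise voxel-wise Pearson correlation, overlap maps) and
    cross-modality accuracy (per-metric correlation and a one-voxel
    thickness error band). Ships a synthetic phantom generator (slabs,
    spherical shells, bent sheets) with analytic ground truth and a
    simulated-rater model so that full precision and accuracy studies run
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    RNifti,
    jsonlite,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    png,
    tiff
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
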