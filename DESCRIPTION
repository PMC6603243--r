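Package: mritexture
Title: Local Multipoint Image Statistics for Brain MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies non-Gaussian spatial structure of structural brain MRI
    slices with the local image statistics used in studies of natural-scene
    statistics and human texture perception. Provides the full pipeline:
    extraction of square regions of interest inside brain parenchyma (convex
    hull of the mask, largest inscribed rectangle, randomized placement),
    ensemble power-spectrum estimation with log-log power-law slope fits,
    spectral whitening by the inverse square root of the ensemble spectrum,
    median binarization per brain, tabulation of 2x2 block colorings, and
    conversion to the ten independent coordinates (gamma; four two-point
    beta; four three-point theta; four-point alpha), with bootstrap
    confidence intervals by slice resampling. A synthetic-data module
    generates power-law Gaussian random fields, maximum-entropy binary
    textures with one prescribed coordinate, and brain-like phantom volumes,
    so every stage is verifiable without access-restricted MRI databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    grDevices,
    utils,
    RNifti,
    jsonlite,
    withr,
    e1071
Suggests:
    testthat (>= 3.0.0),
    pracma
Config/testthat/edition: 3
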