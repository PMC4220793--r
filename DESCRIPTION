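Package: epiquant
Title: Epithelium Percentage Estimation from H&E Micrographs and
    Epithelium-Aware Normalization of Tissue Protein Assays
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Color-based segmentation of hematoxylin-and-eosin (H&E)
    stained tissue micrographs for estimating the epithelium percentage of
    a specimen, and downstream normalization of epithelial-protein
    immunoassay (ELISA) concentrations by that percentage. Pixels are
    clustered into the four dominant H&E colors (white lumen, two pink
    stromal tones, purple epithelium) with k-means, images are tiled into
    20 x 20 pixel grid cells, per-cell color-area ratios are classified
    into epithelial, stromal and luminal tissue by nearest centroid in
    color-ratio space, and the epithelium percentage is computed as
    epithelial area over epithelial-plus-stromal area. Includes a
    synthetic-micrograph generator with per-pixel ground truth,
    cross-validation of the grid-cell classifier, rank-based group
    comparison of assay measurements, and overlay/scatter visualizations.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    grDevices,
    lattice,
    png,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
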