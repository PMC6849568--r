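Package: pccount
Title: Noninvasive Cell Counting in Phase-Contrast Microscopy Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Label-free counting of epithelial cells in phase-contrast
    microscopy images. Cells are localised by subtracting two mean-filtered
    versions of the same image (a small radius that smooths intracellular
    detail and a large radius that brightens cell interiors past their halo
    edges), followed by Otsu thresholding and connected-component analysis.
    Filter radii are selected automatically by an exhaustive search scored
    with discrete-mereotopology (RCC5) relations against nuclear ground
    truth, spurious noise regions are rejected with a linear discriminant
    trained on region morphology and greyscale features, and per-image
    counts are extrapolated to whole-culture totals and growth curves.
    Includes a synthetic scene generator producing paired phase-contrast
    and nuclei images with exact ground truth for testing and calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    e1071,
    jsonlite,
    png,
    stats,
    tiff,
    utils,
    yaml,
    grDevices,
    graphics
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
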