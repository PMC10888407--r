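Package: ihcscore
Title: Unsupervised Stain Separation and Semi-Quantitative Scoring of
    Two-Stain Immunohistochemistry Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fully unsupervised pipeline for scoring bright-field
    immunohistochemistry (IHC) images stained with hematoxylin (nuclei,
    blue) and DAB (protein of interest, brown). Per-image stain color
    vectors are estimated blindly from the optical-density point cloud by
    uncentered principal component analysis with unit-power projections
    followed by angular density-peak detection; concentrations are
    recovered by least-squares color deconvolution, refined using
    stain-dominant pixels, and re-estimated cohort-wide from the average
    stain basis. Four per-image intensity features feed a
    self-initializing p-norm k-means that assigns ordered
    semi-quantitative scores "1+" through "5+". Includes a synthetic
    two-stain cohort generator with known ground truth for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    rlang,
    signal,
    stats,
    tibble,
    tiff,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
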