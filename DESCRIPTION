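Package: neonasal
Title: Automated 3-D CT Morphometry of the Neonatal Nasal Airway
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segments the nasal air column of neonatal head CT volumes and
    measures it. The pipeline isolates the airway with a global -400 HU
    threshold followed by adaptive local thresholding in the -400 to -125 HU
    band and 3-D connectivity filtering, then locates the pyriform-aperture
    and choanae coronal planes, and reports pyriform aperture width with a
    stenosis flag, regional airway volumes (nares, mid-nasal, nasopharynx),
    surface area, and cross-sectional-area profiles with station sampling.
    Includes a parametric CT phantom generator with analytic ground truth,
    segmentation validation metrics (Dice, sensitivity), and nonparametric
    group-comparison statistics for normal, moderate, and severe cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    tibble,
    dplyr,
    tidyr,
    ggplot2,
    generics,
    rlang,
    grDevices,
    jsonlite,
    yaml,
    withr,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
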