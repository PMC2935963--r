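Package: pqctshape
Title: Shape-Sensitive Analysis of Cortical Bone from pQCT Cross-Sections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segments cortical bone from raw peripheral quantitative computed
    tomography (pQCT) cross-section images by seeded flooding above an
    attenuation threshold with morphological cleanup, traces the periosteal
    and endosteal boundaries, and quantifies cross-sectional shape: maximum
    and minimum diameter, axis angle, circumferences, directional and
    whole-ring cortical thickness, cross-sectional areas, and the average
    deviation of the section from an ideal fitted circle and ellipse
    (direct least-squares conic fitting). Also provides the manufacturer
    style circular ring model for comparison, sympercent (log-scale) cohort
    statistics with covariate adjustment, a synthetic phantom generator with
    analytic ground truth for validation, overlay rendering for quality
    control, and a command-line driver for batch analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    tibble,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    png,
    tiff,
    EBImage,
    stats,
    tools,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
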