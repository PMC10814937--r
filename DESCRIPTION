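Package: LesionColor
Title: Quantitative Color Analysis of Clinical Skin-Lesion Photographs
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Colorimetric analysis of clinical photographs of skin lesions,
    aimed at the differential diagnosis of Merkel cell carcinoma against
    look-alike lesions (cherry angiomas, hemangiomas, basal and squamous
    cell carcinomas). Provides lesion border delineation (automatic
    segmentation or operator-placed points closed with a periodic quadratic
    spline), construction of a surrounding normal-skin reference band by
    scaling the border about its centroid, per-region RGB and CIELab mean
    color features with the Individual Typology Angle (ITA), SPSS-convention
    Mann-Whitney U comparisons with an exact small-sample null distribution,
    and single-parameter threshold diagnostics with full confusion-matrix
    reporting. Ships a 46-patient cohort feature table and a synthetic-data
    generator (lesion images with ground-truth masks; multivariate-normal
    feature cohorts) so the whole pipeline is testable offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    grDevices,
    utils,
    tools,
    EBImage,
    pracma,
    png,
    MASS,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    farver,
    jpeg,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
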