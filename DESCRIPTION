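Package: myoatlas
Title: Standardized Pixel-Wise Analysis of Myocardial Injury from Delayed Enhancement MRI Segmentations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Parameterizes the left-ventricular myocardium of segmented
    delayed-enhancement MRI studies in normalized radial, circumferential and
    long-axis coordinates, transports infarct and microvascular-obstruction
    maps onto a common semi-ellipsoid reference geometry, and compares lesion
    patterns between cohort subgroups at every myocardial location using the
    two-sample Hotelling T-squared test, with Bull's eye polar summaries,
    global lesion descriptors before and after standardization, circumferential
    realignment of lesion patterns and a t-SNE population embedding. Includes a
    synthetic cohort generator with known ground truth, readers for CVI42
    workspace contour XML, a NIfTI+JSON study-bundle format, and an end-to-end
    pipeline with run manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    xml2,
    RNifti,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    cluster,
    withr
Config/testthat/edition: 3
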