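Package: woundfluor
Title: Fluorescent Wound-Biomarker Image Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Analysis of handheld fluorescence-microscope images of healing
    skin wounds. Provides fluorescence-intensity-to-pH calibration for the
    SNARF dye read out through the red channel, brightness thresholding and
    k-means pixel clustering of wound beds on colour and position features,
    per-cluster pH dynamics across days with a chi-squared variance test,
    nitric-oxide (DAF-FM, green channel) feature extraction, and normalized
    multi-output ridge regressions that predict the healing day and percent
    re-epithelialization. A seeded synthetic wound-phantom generator produces
    images and feature cohorts with known ground truth so the full pipeline
    is testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    withr,
    yaml
Suggests:
    mclust,
    mgcv,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
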