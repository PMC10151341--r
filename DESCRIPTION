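Package: mammoqc
Title: Automated Breast-Positioning Quality Control for MLO Mammograms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image-processing pipeline for automated quality control of
    breast positioning in mediolateral-oblique (MLO) screening mammograms.
    Locates the inframammary fold by bottom-up window scanning with global
    thresholding, and the nipple-in-profile region by median denoising,
    binarization, binary morphology, border masking and largest-component
    extrema analysis. Detected regions are contrast-enhanced with CLAHE and
    graded on a three-level positioning-quality scale (poor / average /
    excellent) by a small convolutional network with softmax output,
    evaluated by stratified fivefold cross-validation with a summed
    confusion matrix. A seeded phantom generator produces ground-truthed
    synthetic mammograms so every stage is testable without clinical data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    png,
    yaml,
    jsonlite,
    tibble,
    dplyr,
    purrr,
    ggplot2,
    rlang,
    generics,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
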