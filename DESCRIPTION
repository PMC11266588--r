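Package: fundusseg
Title: Level-Set Segmentation and Quantification of Retinal Lesions in
    Infant Fundus Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying retinal lesions (most often haemorrhages)
    in fundus photographs of preterm and at-term infants.  The segmentation
    core is an active contour without edges driven by a local Gaussian
    distribution fitting energy on a level-set field, initialized from a
    user seed circle and evolved by explicit gradient descent; it is robust
    to the smooth multiplicative intensity inhomogeneity typical of wide
    angle neonatal fundus cameras.  Around the core the package provides
    the red/green channel fusion, contrast-limited adaptive histogram
    equalization and edge-preserving bilateral smoothing used to prepare
    images; an image-enhancement suite (geometric-mean brightness
    correction, fixed-aspect circle crop, Gaussian unsharp blend, CLAHE
    variants, channel operations); lesion feature extraction (area,
    perimeter, moment-ellipse axes, intensity statistics); mask-agreement
    scoring (MSE, correlation, Dice, sensitivity/specificity/accuracy);
    a parser, catalog and cohort summariser for a published infant retinal
    image naming convention; and a seeded synthetic fundus generator with
    known lesion masks for testing and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    png,
    jpeg,
    EBImage,
    stats,
    utils,
    grDevices,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    readxl,
    withr
Config/testthat/edition: 3
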