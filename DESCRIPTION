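Package: powdersight
Title: Detecting Flour Adulteration in Spice Powders from Visible Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for detecting chickpea-flour adulteration
    in ground spice powders (black pepper, red pepper, cinnamon) from ordinary
    RGB photographs. Synthesizes powder-mixture images at five adulteration
    levels (0, 5, 15, 30, 50 percent by weight), expands each image into 19
    colour-space channels, extracts a 266-element vector of first-order colour
    statistics and grey-level co-occurrence (Haralick) texture features,
    selects efficient features by sequential forward selection under a
    cross-validated multinomial-deviance criterion, and classifies the
    adulteration level with a Levenberg-Marquardt-trained feed-forward neural
    network and a one-against-one support vector machine, reporting confusion
    matrices and correct classification rates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    e1071,
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
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    farver,
    glmnet,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
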