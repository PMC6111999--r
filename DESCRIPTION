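Package: dermoscan
Title: Skin Nevus Monitoring from Body Photographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A screening pipeline that turns body photographs into per-nevus
    alerts. Candidate skin marks are located with a scale-space (difference of
    Gaussians) key-point detector, screened against background, palette and
    shape filters, extracted as normalized cluster images by recursive
    same-colour region growth, triaged by gray and colour histogram comparison
    against a nevus exemplar database, and classified benign versus suspicious
    by a from-scratch convolutional neural network trained with chain-rule
    backpropagation. A seeded synthetic-scene generator renders skin-textured
    scenes and labelled nevus clusters parameterized by the clinical ABCDE
    warning signs so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    png,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    EBImage,
    yaml,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
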