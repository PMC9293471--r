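Package: mesocond
Title: Mesophyll Conductance Estimation from Gas Exchange, Fluorescence and
    Leaf Anatomy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Estimates mesophyll conductance to CO2 (gm) from combined gas
    exchange and chlorophyll fluorescence measurements with the variable-J
    method, including electron-transport calibration against CO2 fixation
    under non-photorespiratory conditions, Laisk-style estimation of day
    respiration (Rd) and the intercellular photo-compensation point (Ci*),
    cuticular correction of intercellular CO2, Farquhar-von
    Caemmerer-Berry (FvCB) fitting of A-Cc curves for Vcmax and Jmax with
    Arrhenius normalization to 25 degrees C, and a one-dimensional
    serial-resistance model of gm from leaf anatomical traits. A forward
    simulator generates gas-exchange and fluorescence data with known
    ground truth so every estimator can be validated by parameter
    recovery, and a drought pipeline stages records by relative soil water
    content and summarises genotype contrasts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
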