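Package: deltaboost
Title: Delta Log-Normal Boosted Regression Trees for Spatial Abundance
    Modelling and Marine Protected Area Design
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits delta (hurdle) log-normal abundance models with boosted
    regression trees: an occurrence (binomial) ensemble and a positive-catch
    (Gaussian on the natural log) ensemble are fitted over a hyperparameter
    grid with cross-validated early stopping, simplified by backward
    elimination, and combined on a prediction grid with Duan's smearing
    retransformation. Companion tools score survey representativeness of the
    prediction grid, amalgamate multi-species surfaces into conservation
    priority maps, propose candidate closed areas (MPAs) that protect
    escapement-biomass targets while minimising displacement of a mapped
    stressor such as fishing effort, and quantify between-run prediction
    uncertainty as a per-cell coefficient of variation. A synthetic-data
    generator with known ground truth supports testing and calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
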