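Package: pollenlevels
Title: Spatiotemporal Prediction of High Allergenic Pollen Concentration Levels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting days with high airborne Corylus (hazel),
    Alnus (alder) and Betula (birch) pollen concentration levels from gridded
    daily meteorology. Implements 99-percent-method pollen season delimitation,
    growing-degree-day and lagged-window feature engineering, imbalance-aware
    random-forest classification with an optimized probability threshold,
    dual temporal/spatial evaluation (Kappa, sensitivity, specificity, PPV,
    NPV), and grid-wide predictive mapping. Ships a synthetic-world generator
    (seasonal grid meteorology plus station pollen counts with a known
    GDD-by-evaporation response) so the whole pipeline can be exercised and
    tested without proprietary monitoring data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    geosphere,
    ggplot2,
    purrr,
    ranger,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    zoo
Suggests:
    e1071,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
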