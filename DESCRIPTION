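Package: sdmdrivers
Title: Decadal Species Distribution Hindcasting and Climate Versus
    Land-Use Driver Attribution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for reconstructing and projecting decadal species
    distributions at a northern range edge from a fixed logistic species
    distribution model. Computes a winter severity index and growing
    season length from daily climate series, composites decadal
    land-use/land-cover landscapes (cumulative well pads, age-limited
    forestry cut blocks, epoch-mapped agriculture, land-cover
    reconciliation), applies the model on a grid, attributes
    between-decade probability changes to climate or land use by
    counterfactual covariate freezing, validates predictions
    (sensitivity, specificity, true skill statistic, AUC, calibration),
    and forecasts future decades by per-cell linear climate trend
    extrapolation. Includes a synthetic-data generator so the full
    pipeline is exercisable without external GIS or climate inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    rlang
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
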