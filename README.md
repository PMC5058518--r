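# sdmdrivers

Decadal species-distribution hindcasting with climate-versus-land-use
driver attribution, for range-edge systems such as white-tailed deer
(*Odocoileus virginianus*) expanding into the western boreal forest.

A species' range edge can move because the climate ameliorates, because
human land use creates habitat, or both at once. `sdmdrivers` takes a
fixed logistic species distribution model (SDM), reconstructs the
covariate landscape of each past decade, predicts the probability of
presence on a grid, and then isolates each driver's contribution with
counterfactual "no-change" landscapes: holding climate at the previous
decade isolates the land-use effect, and vice versa, with the larger
absolute probability difference naming the driver per cell. The same
machinery projects future decades by per-cell linear climate trends with
land use frozen. It is aimed at spatial ecologists who want this whole
chain — indices, landscape compositing, prediction, attribution,
validation, forecasting — testable end to end without proprietary GIS
inputs, via a built-in synthetic-data generator.

## The model

Probability of presence in a grid cell is the inverse logit of

```
logit p = -10.12 + 4.98·Deciduous - 3.11·Wetland + 9.79·Footprint
          - 0.07·WSI + 0.11·GS
```

where Deciduous, Wetland and Footprint are per-cell proportions, WSI is
the cumulative-mean winter severity index (days per winter, November–
April, with minimum temperature below −17.7 °C and/or snow depth above
38 cm, averaged from 1961 to the decade of interest) and GS the
cumulative-mean growing season length (days; onset at the first 5-day
run of mean temperature ≥ 5 °C from March 1, ending at the first
minimum ≤ −2 °C after August 1; averaged from 1950). Probabilities at
or above the training prevalence 0.73 (= 218/299) are classified as
presence. Coefficients, thresholds and index definitions are all
configuration.

## Worked example

Simulate a 6×6-cell half-century, hindcast four decades, attribute the
1990s→2000s change, validate, and forecast to 2050:

```r
library(sdmdrivers)

cfg  <- synthetic_config(grid_rows = 6, grid_cols = 6, seed = 1)
grid <- config_grid(cfg)

climate <- generate_climate(cfg)
events  <- generate_landuse_history(cfg)
cover   <- generate_landcover(cfg)
wsi <- annual_wsi(climate)
gs  <- annual_growing_season(climate)

land <- lapply(c(1970, 1980, 1990, 2000), function(d)
  assemble_landscape(grid, events, cover, wsi, gs, d))
names(land) <- c(1970, 1980, 1990, 2000)

pred2000 <- predict_probability(land[["2000"]])
summary(pred2000$p)
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
#>  0.5470  0.7421  0.9407  0.8631  0.9997  0.9999

summarize_attribution(
  attribute_change(land[["1990"]], land[["2000"]], threshold = 0.73))
#> Attribution 1990 -> 2000
#> Cells: 36; with probability increase: 31
#>   climate-driven:  27 (87.1%)
#>   land-use-driven: 4 (12.9%)
#> Threshold crossings up: 2 (climate 2, land use 0); down: 0
```

Of the 31 cells whose predicted probability rose between the decades,
27 (87%) are attributed to the simulated winter-warming/growing-season
trend and 4 to footprint growth; two cells crossed the 0.73 presence
threshold, both climate-driven — the synthetic half-century behaves
like the range-edge system it emulates.

```r
obs <- sample_observations(pred2000, n_sites = 30, seed = 99)
validation_stats(obs$presence,
                 pred2000$p[match(obs$cell_id, pred2000$cell_id)],
                 threshold = 0.73)
#>     data_set  n n_presence prevalence       auc tss sensitivity ...
#> 1 validation 30         24        0.8 0.8680556 0.5   0.8333333 ...

scen <- forecast_scenario(land[["2000"]], wsi, gs)
fc2050 <- forecast_decade(scen, 2050, threshold = 0.73)
range_change(classify_presence(pred2000, 0.73), fc2050$presence,
             cell_area_km2 = 10)
#> $gained_km2
#> [1] 90
#> $lost_km2
#> [1] 0
```

The validation row mirrors a standard SDM accuracy table (AUC 0.87, TSS
0.5 on observations sampled from the model's own predictions), and the
forecast predicts 9 cells (90 km²) of range gain by the 2050s under the
extrapolated climate trends with land use frozen at the 2000s.

The same run is available as a shell pipeline
(`inst/scripts/pipeline.R`) over a YAML configuration
(`inst/extdata/demo-config.yaml`), with stages `simulate`, `indices`,
`landscape`, `hindcast`, `attribute`, `validate`, `forecast`, writing
delimited tables, matrix rasters with JSON sidecars, and a manifest
with a configuration hash for bit-identical reruns.

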