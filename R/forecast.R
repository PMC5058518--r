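#' Build a forecast scenario from a base decade
#'
#' Freezes land use and land cover at the base decade's landscape and
#' fits per-cell linear trends to the observed annual winter severity
#' and growing season series (optionally restricted to the year ranges
#' used in the reference analysis: winter severity 1961--2002, growing
#' season 1950--1999). Future decades are then predicted by
#' [forecast_decade()].
#'
#' @param base_landscape the `decadal_landscape` of the base decade
#'   (e.g. the 2000s); its decade label is taken from the `"decade"`
#'   attribute unless `base_decade` is given.
#' @param wsi_annual,gs_annual observed annual index tables (`cell_id`,
#'   `year`, `value`).
#' @param base_decade decade label of `base_landscape` (optional
#'   override).
#' @param wsi_years,gs_years optional integer vectors restricting the
#'   years used for trend fitting.
#' @param wsi_base_year,gs_base_year base years of the cumulative climate
#'   means (must match those used for the hindcast landscapes).
#' @return List of class `forecast_scenario`.
#' @export
forecast_scenario <- function(base_landscape, wsi_annual, gs_annual,
                              base_decade = NULL,
                              wsi_years = NULL, gs_years = NULL,
                              wsi_base_year = 1961L, gs_base_year = 1950L) {
  base_decade <- base_decade %||% attr(base_landscape, "decade")
  if (is.null(base_decade))
    stopf("forecast_scenario: base decade label unavailable")
  sub_years <- function(annual, yrs)
    if (is.null(yrs)) annual else annual[annual$year %in% yrs, ]
  out <- list(
    base_decade = as.integer(base_decade),
    base_landscape = base_landscape,
    wsi_annual = wsi_annual, gs_annual = gs_annual,
    wsi_trend = fit_trend(sub_years(wsi_annual, wsi_years)),
    gs_trend = fit_trend(sub_years(gs_annual, gs_years)),
    wsi_base_year = wsi_base_year, gs_base_year = gs_base_year)
  class(out) <- "forecast_scenario"
  out
}

# cumulative mean from base_year..end_year blending observed annual
# values with trend extrapolation for years past the observed record
blended_cumulative_mean <- function(annual, trend, base_year, end_year,
                                    floor = 0, cap = Inf) {
  years <- base_year:end_year
  cells <- sort(unique(annual$cell_id))
  last_obs <- max(annual$year)
  obs_years <- years[years <= last_obs]
  fut_years <- years[years > last_obs]
  # observed part must be complete
  obs <- cumulative_mean(annual, base_year, max(obs_years))
  obs <- obs[match(cells, obs$cell_id), ]
  total <- obs$mean * length(obs_years)
  if (length(fut_years)) {
    tr <- trend[match(cells, trend$cell_id), ]
    if (anyNA(tr$cell_id))
      stopf("forecast: trend missing for some cells")
    for (y in fut_years) {
      v <- tr$intercept + tr$slope * (y - tr$reference_year)
      total <- total + pmin(pmax(v, floor), cap)
    }
  }
  data.frame(cell_id = cells, mean = total / length(years))
}

#' Predict a future decade under extrapolated climate
#'
#' Climate covariates for the target decade are cumulative means from
#' the base years to the decade label, using observed annual values
#' where available and per-cell linear trend extrapolations beyond the
#' observed record (winter severity floored at 0; growing season floored
#' at 0 and capped at 366). Land use and land cover stay frozen at the
#' base decade. At the base decade itself this reproduces the hindcast
#' prediction exactly.
#'
#' @param scenario a [forecast_scenario()].
#' @param decade target decade label (>= the base decade).
#' @param coef an [sdm_coefficients()].
#' @param threshold presence threshold in (0, 1).
#' @return List with `landscape` (the composed `decadal_landscape`),
#'   `prediction` (a `prediction_grid`) and `presence` (from
#'   [classify_presence()]).
#' @export
forecast_decade <- function(scenario, decade, coef = sdm_coefficients(),
                            threshold = 0.73) {
  stopifnot(inherits(scenario, "forecast_scenario"))
  decade <- check_count(decade, "decade", lower = 0L)
  if (decade < scenario$base_decade)
    stopf("forecast_decade: decade %d precedes base decade %d",
          decade, scenario$base_decade)
  base <- scenario$base_landscape
  wsi <- blended_cumulative_mean(scenario$wsi_annual, scenario$wsi_trend,
                                 scenario$wsi_base_year, decade, floor = 0)
  gs <- blended_cumulative_mean(scenario$gs_annual, scenario$gs_trend,
                                scenario$gs_base_year, decade,
                                floor = 0, cap = 366)
  land <- base
  land$wsi_mean <- wsi$mean[match(base$cell_id, wsi$cell_id)]
  land$gs_mean <- gs$mean[match(base$cell_id, gs$cell_id)]
  if (anyNA(land$wsi_mean) || anyNA(land$gs_mean))
    stopf("forecast_decade: climate means missing for some cells")
  attr(land, "decade") <- decade
  pred <- predict_probability(land, coef)
  list(landscape = land, prediction = pred,
       presence = classify_presence(pred, threshold))
}

#' Range area gained and lost between two presence layers
#'
#' @param base,future presence layers from [classify_presence()] on the
#'   same grid.
#' @param cell_area_km2 area of one cell in km^2.
#' @return List `gained_km2`, `lost_km2`, `net_km2`, `n_gained`,
#'   `n_lost`.
#' @export
range_change <- function(base, future, cell_area_km2) {
  check_columns(base, c("cell_id", "presence"), "base")
  check_columns(future, c("cell_id", "presence"), "future")
  if (nrow(base) != nrow(future) || !all(base$cell_id == future$cell_id))
    stopf("range_change: presence layers are on different grids")
  check_number(cell_area_km2, "cell_area_km2", lower = 0)
  gained <- sum(!base$presence & future$presence)
  lost <- sum(base$presence & !future$presence)
  list(gained_km2 = gained * cell_area_km2, lost_km2 = lost * cell_area_km2,
       net_km2 = (gained - lost) * cell_area_km2,
       n_gained = gained, n_lost = lost)
}
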