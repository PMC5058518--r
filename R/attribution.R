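#' Counterfactual landscape holding one factor at its previous state
#'
#' Builds the "no-change" landscape used to isolate a driver between two
#' decades: with `hold = "climate"` the current land-use/land-cover
#' covariates are combined with the previous decade's climate means
#' (climate did not change); with `hold = "land_use"` the current climate
#' means are combined with the previous decade's footprint and land cover
#' (land use did not change). Land cover travels with the land-use factor
#' because development is what erases it.
#'
#' @param prev,curr `decadal_landscape` data frames on the same grid.
#' @param hold which factor to freeze at `prev`: `"climate"` or
#'   `"land_use"`.
#' @return A `decadal_landscape` with the mixed covariates, labeled with
#'   `curr`'s decade.
#' @export
counterfactual_landscape <- function(prev, curr,
                                     hold = c("climate", "land_use")) {
  hold <- match.arg(hold)
  cols <- c("cell_id", "prop_deciduous", "prop_wetland", "prop_footprint",
            "wsi_mean", "gs_mean")
  check_columns(prev, cols, "prev")
  check_columns(curr, cols, "curr")
  if (nrow(prev) != nrow(curr) || !all(prev$cell_id == curr$cell_id))
    stopf("counterfactual_landscape: `prev` and `curr` are on different grids")
  out <- curr
  if (hold == "climate") {
    out$wsi_mean <- prev$wsi_mean
    out$gs_mean <- prev$gs_mean
  } else {
    out$prop_deciduous <- prev$prop_deciduous
    out$prop_wetland <- prev$prop_wetland
    out$prop_footprint <- prev$prop_footprint
  }
  out
}

#' Attribute between-decade probability change to climate or land use
#'
#' For each cell, computes the actual probability change between two
#' decadal landscapes and the two counterfactual differences:
#' `delta_due_climate = p(curr) - p(climate held at prev)` and
#' `delta_due_landuse = p(curr) - p(land use held at prev)`. The driver
#' label is the factor with the larger absolute counterfactual
#' difference; `"none"` when both are exactly zero. Ties in absolute
#' value (measure-zero on continuous covariates) are labeled climate and
#' flagged in the `tie` column so they can be tallied separately.
#'
#' Because the inverse logit is nonlinear, the two counterfactual
#' differences need not sum to the actual change; all three are reported
#' so the discrepancy stays visible.
#'
#' Cells whose presence classification (at `threshold`, inclusive)
#' differs between the decades are flagged as threshold crossings, with
#' the crossing direction and the crossing's driver label recorded.
#'
#' @param prev,curr `decadal_landscape` data frames on the same grid.
#' @param coef an [sdm_coefficients()].
#' @param threshold presence threshold in (0, 1).
#' @return An `attribution_grid` data frame with columns `cell_id`,
#'   `p_prev`, `p_curr`, `delta_actual`, `delta_due_climate`,
#'   `delta_due_landuse`, `driver`, `tie`, `crossed`, `direction`,
#'   `crossing_driver`.
#' @export
attribute_change <- function(prev, curr, coef = sdm_coefficients(),
                             threshold = 0.73) {
  p_prev <- predict_probability(prev, coef)$p
  p_curr <- predict_probability(curr, coef)$p
  p_hold_clim <- predict_probability(
    counterfactual_landscape(prev, curr, "climate"), coef)$p
  p_hold_lu <- predict_probability(
    counterfactual_landscape(prev, curr, "land_use"), coef)$p

  d_clim <- p_curr - p_hold_clim
  d_lu <- p_curr - p_hold_lu
  driver <- ifelse(d_clim == 0 & d_lu == 0, "none",
                   ifelse(abs(d_clim) >= abs(d_lu), "climate", "land_use"))
  tie <- driver != "none" & abs(d_clim) == abs(d_lu)

  pres_prev <- p_prev >= threshold
  pres_curr <- p_curr >= threshold
  crossed <- pres_prev != pres_curr
  direction <- ifelse(!crossed, "none", ifelse(pres_curr, "up", "down"))

  out <- data.frame(
    cell_id = prev$cell_id, p_prev = p_prev, p_curr = p_curr,
    delta_actual = p_curr - p_prev,
    delta_due_climate = d_clim, delta_due_landuse = d_lu,
    driver = driver, tie = tie, crossed = crossed, direction = direction,
    crossing_driver = ifelse(crossed, driver, "none"))
  attr(out, "decade_pair") <- c(attr(prev, "decade") %||% NA,
                                attr(curr, "decade") %||% NA)
  attr(out, "threshold") <- threshold
  class(out) <- c("attribution_grid", class(out))
  out
}

#' Summarize an attribution grid
#'
#' Tallies, over the cells whose predicted probability increased, how
#' many are labeled climate-driven versus land-use-driven (counts and
#' percentages; cells are equal-area so cell percentages equal area
#' percentages), plus threshold-crossing counts by driver and direction.
#' Zero denominators are reported as `NA` percentages rather than
#' dropped.
#'
#' @param attr_grid an `attribution_grid` from [attribute_change()].
#' @return A list of class `attribution_summary`.
#' @export
summarize_attribution <- function(attr_grid) {
  check_columns(attr_grid, c("delta_actual", "driver", "crossed",
                             "direction"), "attr_grid")
  inc <- attr_grid[attr_grid$delta_actual > 0, ]
  n_inc <- nrow(inc)
  n_inc_clim <- sum(inc$driver == "climate")
  n_inc_lu <- sum(inc$driver == "land_use")
  up <- attr_grid[attr_grid$crossed & attr_grid$direction == "up", ]
  down <- attr_grid[attr_grid$crossed & attr_grid$direction == "down", ]
  pct <- function(k, n) if (n > 0) 100 * k / n else NA_real_
  out <- list(
    decade_pair = attr(attr_grid, "decade_pair"),
    n_cells = nrow(attr_grid),
    n_increase = n_inc,
    n_increase_climate = n_inc_clim,
    n_increase_landuse = n_inc_lu,
    pct_increase_climate = pct(n_inc_clim, n_inc),
    pct_increase_landuse = pct(n_inc_lu, n_inc),
    n_ties = sum(attr_grid$tie),
    n_crossed_up = nrow(up),
    n_crossed_up_climate = sum(up$driver == "climate"),
    n_crossed_up_landuse = sum(up$driver == "land_use"),
    n_crossed_down = nrow(down),
    n_crossed_down_climate = sum(down$driver == "climate"),
    n_crossed_down_landuse = sum(down$driver == "land_use"))
  class(out) <- "attribution_summary"
  out
}

#' @export
print.attribution_summary <- function(x, ...) {
  dp <- x$decade_pair
  if (!is.null(dp) && !all(is.na(dp)))
    cat(sprintf("Attribution %s -> %s\n", dp[1], dp[2]))
  cat(sprintf("Cells: %d; with probability increase: %d\n",
              x$n_cells, x$n_increase))
  cat(sprintf("  climate-driven:  %d (%s%%)\n", x$n_increase_climate,
              formatC(x$pct_increase_climate, digits = 1, format = "f")))
  cat(sprintf("  land-use-driven: %d (%s%%)\n", x$n_increase_landuse,
              formatC(x$pct_increase_landuse, digits = 1, format = "f")))
  cat(sprintf("Threshold crossings up: %d (climate %d, land use %d); down: %d\n",
              x$n_crossed_up, x$n_crossed_up_climate,
              x$n_crossed_up_landuse, x$n_crossed_down))
  if (x$n_ties) cat(sprintf("Ties (labeled climate): %d\n", x$n_ties))
  invisible(x)
}
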