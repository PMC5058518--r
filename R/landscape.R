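# Decade conventions: decade label d covers calendar years [d, d+9];
# the footprint snapshot is taken at the decade's last calendar year and
# the climate covariates are cumulative means from their base year to the
# decade label (the "beginning of the decade of interest").

decade_end <- function(decade) decade + 9L

#' Per-cell land-use footprint proportion for one decade
#'
#' Composites the three industrial footprints into a per-cell developed
#' proportion for the decade labeled `decade` (covering calendar years
#' `decade..decade+9`):
#' \itemize{
#'   \item \strong{Well pads} are cumulative: every well with a
#'     development year up to the decade end contributes (well sites are
#'     not reclaimed). Undated wells are treated as present throughout.
#'   \item \strong{Cut blocks} age out: a cut contributes only while its
#'     browse is young enough, i.e. when
#'     `decade - cut_age_years <= cut_year <= decade + 9`. With the
#'     default 30-year age, cuts before 1970 are excluded from the 2000s
#'     footprint. Cuts with unknown year are included iff
#'     `include_undated_cuts` (the reference analysis ran both ways and
#'     kept the maximum footprint).
#'   \item \strong{Agriculture} is mapped from census-epoch layers: each
#'     decade uses the earliest epoch at or after its end year (else the
#'     latest epoch), together with all earlier epochs, since farmland
#'     once developed is assumed to remain on the landscape. Per-cell
#'     agriculture area is the maximum across included epochs (epochs
#'     overlay the same land, they do not add).
#' }
#' Overlap among layers is handled by capping the per-cell union at the
#' cell area before converting to a proportion, so footprint never
#' exceeds 1.
#'
#' @param events a `landuse_events` list with data frames `wells`
#'   (`cell_id`, `year`, `area_km2`), `cutblocks` (`cell_id`, `year`
#'   possibly `NA`, `area_km2`) and `agriculture` (`cell_id`,
#'   `epoch_year`, `area_km2`), e.g. from
#'   [generate_landuse_history()].
#' @param grid grid from [make_grid()].
#' @param decade decade label (e.g. 1970 for 1970--1979).
#' @param include_undated_cuts include cut blocks with unknown year?
#' @param cut_age_years age, in years from the decade label, beyond
#'   which a cut block no longer contributes (default 30).
#' @param agri_epoch optional explicit epoch year to use for the decade,
#'   overriding the default mapping.
#' @return Data frame `cell_id`, `prop_footprint` in cell order.
#' @export
footprint_for_decade <- function(events, grid, decade,
                                 include_undated_cuts = TRUE,
                                 cut_age_years = 30L,
                                 agri_epoch = NULL) {
  stopifnot(is.list(events))
  check_columns(grid, c("cell_id", "area_km2"), "grid")
  decade <- check_count(decade, "decade", lower = 0L)
  dend <- decade_end(decade)
  area <- numeric(nrow(grid))
  names(area) <- as.character(grid$cell_id)

  add_layer <- function(area, df) {
    if (!nrow(df)) return(area)
    agg <- rowsum(df$area_km2, df$cell_id)
    idx <- match(rownames(agg), names(area))
    if (anyNA(idx)) stopf("footprint_for_decade: event cell_id not in grid")
    area[idx] <- area[idx] + as.vector(agg)
    area
  }

  wells <- events$wells
  if (!is.null(wells) && nrow(wells)) {
    keep <- is.na(wells$year) | wells$year <= dend
    area <- add_layer(area, wells[keep, ])
  }
  cuts <- events$cutblocks
  if (!is.null(cuts) && nrow(cuts)) {
    dated <- !is.na(cuts$year) & cuts$year >= decade - cut_age_years &
      cuts$year <= dend
    keep <- dated | (include_undated_cuts & is.na(cuts$year))
    area <- add_layer(area, cuts[keep, ])
  }
  agri <- events$agriculture
  if (!is.null(agri) && nrow(agri)) {
    epochs <- sort(unique(agri$epoch_year))
    use <- agri_epoch %||% {
      at_or_after <- epochs[epochs >= dend]
      if (length(at_or_after)) at_or_after[1] else max(epochs)
    }
    sub <- agri[agri$epoch_year <= use, ]
    # union across epochs: same land, take the maximal per-cell coverage
    mx <- tapply(sub$area_km2, sub$cell_id, max)
    area <- add_layer(area, data.frame(cell_id = names(mx),
                                       area_km2 = as.vector(mx)))
  }
  prop <- pmin(area, grid$area_km2) / grid$area_km2
  data.frame(cell_id = grid$cell_id, prop_footprint = unname(prop))
}

#' Reconcile land cover with the land-use footprint
#'
#' Where the summed proportions of footprint, deciduous forest and
#' wetland exceed one (a resolution artifact of overlaying layers), the
#' total is reduced to one by shrinking the two land-cover proportions
#' --- never the footprint --- in proportion to their coverage. Land-use
#' development thus functionally erases land cover. If the sum is at most
#' one the inputs pass through unchanged; a footprint above one on its
#' own is an error.
#'
#' @param prop_footprint,prop_deciduous,prop_wetland numeric vectors in
#'   `[0, 1]` (recycled to a common length).
#' @return Data frame `prop_deciduous`, `prop_wetland` (adjusted).
#' @examples
#' reconcile_landcover(0.5, 0.4, 0.2) # deciduous 1/3, wetland 1/6
#' @export
reconcile_landcover <- function(prop_footprint, prop_deciduous,
                                prop_wetland) {
  n <- max(length(prop_footprint), length(prop_deciduous),
           length(prop_wetland))
  fp <- rep_len(prop_footprint, n)
  dec <- rep_len(prop_deciduous, n)
  wet <- rep_len(prop_wetland, n)
  if (anyNA(fp) || any(fp < -1e-9))
    stopf("reconcile_landcover: footprint must be non-negative")
  if (any(fp > 1 + 1e-9))
    stopf("reconcile_landcover: footprint alone exceeds 1")
  for (v in list(dec, wet))
    if (anyNA(v) || any(v < -1e-9 | v > 1 + 1e-9))
      stopf("reconcile_landcover: proportions must be in [0, 1]")
  excess <- pmax(fp + dec + wet - 1, 0)
  tot <- dec + wet
  share <- ifelse(tot > 0, excess / tot, 0)
  data.frame(prop_deciduous = pmax(dec * (1 - share), 0),
             prop_wetland = pmax(wet * (1 - share), 0))
}

#' Assemble the decadal covariate landscape
#'
#' Builds the five-covariate landscape the distribution model consumes
#' for one decade: reconciled deciduous and wetland proportions, total
#' land-use footprint at the decade end, and cumulative mean winter
#' severity (from `wsi_base_year`, default 1961) and growing season
#' length (from `gs_base_year`, default 1950) up to the decade label.
#'
#' @param grid grid from [make_grid()].
#' @param events land-use events (see [footprint_for_decade()]).
#' @param landcover data frame `cell_id`, `prop_deciduous`,
#'   `prop_wetland`.
#' @param wsi_annual,gs_annual annual index tables (`cell_id`, `year`,
#'   `value`).
#' @param decade decade label.
#' @param wsi_base_year,gs_base_year base years of the cumulative climate
#'   means.
#' @inheritParams footprint_for_decade
#' @return A `decadal_landscape` data frame with columns `cell_id`,
#'   `prop_deciduous`, `prop_wetland`, `prop_footprint`, `wsi_mean`,
#'   `gs_mean`; the decade label is carried as attribute `"decade"`.
#' @export
assemble_landscape <- function(grid, events, landcover, wsi_annual,
                               gs_annual, decade,
                               wsi_base_year = 1961L, gs_base_year = 1950L,
                               include_undated_cuts = TRUE,
                               cut_age_years = 30L, agri_epoch = NULL) {
  check_columns(landcover, c("cell_id", "prop_deciduous", "prop_wetland"),
                "landcover")
  decade <- check_count(decade, "decade", lower = 0L)
  fp <- footprint_for_decade(events, grid, decade, include_undated_cuts,
                             cut_age_years, agri_epoch)
  lc <- landcover[match(grid$cell_id, landcover$cell_id), ]
  if (anyNA(lc$cell_id)) stopf("assemble_landscape: landcover missing cells")
  wsi <- cumulative_mean(wsi_annual, wsi_base_year, decade)
  gs <- cumulative_mean(gs_annual, gs_base_year, decade)
  wsi_v <- wsi$mean[match(grid$cell_id, wsi$cell_id)]
  gs_v <- gs$mean[match(grid$cell_id, gs$cell_id)]
  if (anyNA(wsi_v) || anyNA(gs_v))
    stopf("assemble_landscape: climate indices missing for some cells")
  adj <- reconcile_landcover(fp$prop_footprint, lc$prop_deciduous,
                             lc$prop_wetland)
  out <- data.frame(cell_id = grid$cell_id,
                    prop_deciduous = adj$prop_deciduous,
                    prop_wetland = adj$prop_wetland,
                    prop_footprint = fp$prop_footprint,
                    wsi_mean = wsi_v, gs_mean = gs_v)
  attr(out, "decade") <- decade
  class(out) <- c("decadal_landscape", class(out))
  out
}
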