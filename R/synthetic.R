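#' Configuration for the synthetic data generator
#'
#' Defines the study conditions emulated by the generator: a rectangular
#' grid of equal-area cells, a span of calendar years, per-cell linear
#' trends in annual winter severity (index points/year) and growing
#' season length (days/year), daily weather noise, a seasonal snow
#' course, clustered growth of three land-use industries, and optional
#' imperfect detection for sampled observations.
#'
#' Defaults follow the boreal range-edge setting the pipeline targets:
#' winter severity starting near 145 index points and declining 0.8
#' points/year (observed per-cell declines in the region span roughly
#' 0.16--2.2), so that decadal cumulative means pass through the
#' presence-threshold region over the simulated half-century,
#' growing season near 163 days lengthening 0.15 days/year (observed
#' -0.06 to +0.38), and daily climate records starting in 1950 so both
#' cumulative-mean base years (1950 for growing season, 1961 for winter
#' severity) are covered.
#'
#' @param grid_rows,grid_cols grid dimensions (cells).
#' @param cell_area_km2 area per cell, km^2.
#' @param years inclusive range of calendar years with daily climate.
#' @param wsi_base mean annual winter severity (index points) in the
#'   first year.
#' @param wsi_trend index points/year; scalar or one value per cell.
#' @param wsi_sd interannual standard deviation of winter severity.
#' @param gs_base mean growing season length (days) in the first year.
#' @param gs_trend days/year; scalar or one value per cell.
#' @param gs_sd interannual standard deviation of growing season length.
#' @param gs_start_doy nominal growing-season onset (day of year).
#' @param daily_noise_sd daily temperature noise, degrees C.
#' @param snow_peak_cm peak of the baseline seasonal snow course, cm
#'   (kept below the winter-severity snow threshold; qualifying snow
#'   days are planted above it).
#' @param wells_per_year,wells_growth Poisson mean of new wells in the
#'   first year and exponential growth rate per year.
#' @param well_area_km2 developed area per well pad (default 100 m^2).
#' @param cuts_per_year Poisson mean of new cut blocks per year.
#' @param cut_area_km2 area per cut block.
#' @param cut_undated_frac fraction of cut blocks with unknown year.
#' @param agri_epochs census epoch years of the agriculture layers.
#' @param agri_frac fraction of grid rows (from the southern edge)
#'   inside the agricultural zone at each epoch; same length as
#'   `agri_epochs`, non-decreasing.
#' @param agri_cover_frac fraction of a zone cell's area that is farmed.
#' @param landuse_clustering probability in `[0, 1]` that a new well or
#'   cut block is placed next to an existing development nucleus rather
#'   than uniformly at random; 0 gives spatially unstructured growth.
#' @param n_nuclei number of development nuclei.
#' @param detection_prob probability a truly present species is detected
#'   at a sampled site.
#' @param seed integer seed; identical seed and configuration give
#'   bit-identical outputs.
#' @return Validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(grid_rows = 6L, grid_cols = 6L,
                             cell_area_km2 = 10,
                             years = 1950:2009,
                             wsi_base = 145, wsi_trend = -0.8, wsi_sd = 8,
                             gs_base = 163, gs_trend = 0.15, gs_sd = 5,
                             gs_start_doy = 100L,
                             daily_noise_sd = 2,
                             snow_peak_cm = 20,
                             wells_per_year = 2, wells_growth = 0.08,
                             well_area_km2 = 1e-4,
                             cuts_per_year = 1.5, cut_area_km2 = 0.5,
                             cut_undated_frac = 0.3,
                             agri_epochs = c(1991L, 2006L),
                             agri_frac = c(0.25, 0.35),
                             agri_cover_frac = 0.8,
                             landuse_clustering = 0.8, n_nuclei = 3L,
                             detection_prob = 1, seed = 1L) {
  grid_rows <- check_count(grid_rows, "grid_rows")
  grid_cols <- check_count(grid_cols, "grid_cols")
  check_number(cell_area_km2, "cell_area_km2", lower = 1e-12)
  years <- as.integer(years)
  if (!length(years) || anyNA(years) || any(diff(years) != 1L))
    stopf("`years` must be a non-empty consecutive year range")
  n_cells <- grid_rows * grid_cols
  for (nm in c("wsi_trend", "gs_trend")) {
    v <- get(nm)
    if (!length(v) %in% c(1L, n_cells))
      stopf("`%s` must be a scalar or one value per cell (%d)", nm, n_cells)
    if (anyNA(v) || !is.numeric(v)) stopf("`%s` must be numeric", nm)
  }
  check_number(wsi_base, "wsi_base", lower = 0)
  check_number(wsi_sd, "wsi_sd", lower = 0)
  check_number(gs_base, "gs_base", lower = 0)
  check_number(gs_sd, "gs_sd", lower = 0)
  check_count(gs_start_doy, "gs_start_doy", lower = 65L)
  if (gs_start_doy > 160L) stopf("`gs_start_doy` must be <= 160")
  check_number(daily_noise_sd, "daily_noise_sd", lower = 0)
  check_number(snow_peak_cm, "snow_peak_cm", lower = 0)
  check_number(wells_per_year, "wells_per_year", lower = 0)
  check_number(wells_growth, "wells_growth", lower = -1)
  check_number(well_area_km2, "well_area_km2", lower = 0)
  check_number(cuts_per_year, "cuts_per_year", lower = 0)
  check_number(cut_area_km2, "cut_area_km2", lower = 0, upper = cell_area_km2)
  check_prob(cut_undated_frac, "cut_undated_frac")
  if (length(agri_epochs) != length(agri_frac))
    stopf("`agri_epochs` and `agri_frac` must have equal length")
  if (any(diff(agri_frac) < 0)) stopf("`agri_frac` must be non-decreasing")
  for (f in agri_frac) check_prob(f, "agri_frac")
  check_prob(agri_cover_frac, "agri_cover_frac")
  check_prob(landuse_clustering, "landuse_clustering")
  check_count(n_nuclei, "n_nuclei")
  check_prob(detection_prob, "detection_prob")
  seed <- check_count(seed, "seed", lower = 0L)

  out <- list(grid_rows = grid_rows, grid_cols = grid_cols,
              cell_area_km2 = cell_area_km2, years = years,
              wsi_base = wsi_base, wsi_trend = wsi_trend, wsi_sd = wsi_sd,
              gs_base = gs_base, gs_trend = gs_trend, gs_sd = gs_sd,
              gs_start_doy = as.integer(gs_start_doy),
              daily_noise_sd = daily_noise_sd,
              snow_peak_cm = snow_peak_cm,
              wells_per_year = wells_per_year, wells_growth = wells_growth,
              well_area_km2 = well_area_km2,
              cuts_per_year = cuts_per_year, cut_area_km2 = cut_area_km2,
              cut_undated_frac = cut_undated_frac,
              agri_epochs = as.integer(agri_epochs), agri_frac = agri_frac,
              agri_cover_frac = agri_cover_frac,
              landuse_clustering = landuse_clustering,
              n_nuclei = as.integer(n_nuclei),
              detection_prob = detection_prob, seed = seed)
  class(out) <- "synthetic_config"
  out
}

#' Grid implied by a synthetic configuration
#' @param config a [synthetic_config()].
#' @return A grid data frame (see [make_grid()]).
#' @export
config_grid <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  make_grid(config$grid_rows, config$grid_cols, config$cell_area_km2)
}

#' Generate daily gridded climate series
#'
#' Produces, per cell, a daily record of minimum temperature, mean
#' temperature and snow depth whose derived annual winter severity and
#' growing season series follow the configured linear trends. The
#' generator is constructive: for each winter it draws a target index
#' value from the trend line plus interannual noise, then plants exactly
#' that many qualifying days (cold, deep-snow, or both) inside the
#' November--April window; for each calendar year it draws a target
#' growing season length and plants the onset run and the season-ending
#' frost accordingly. Daily temperature noise perturbs all records but
#' planting margins keep each day's qualification status as drawn, so
#' ordinary least squares on the derived annual series recovers the
#' configured trends up to the interannual noise.
#'
#' @param config a [synthetic_config()].
#' @return Data frame `cell_id`, `date`, `tmin`, `tmean`, `snow_cm`
#'   with `tmin <= tmean` and `snow_cm >= 0` everywhere.
#' @export
generate_climate <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  grid <- config_grid(config)
  n_cells <- nrow(grid)
  wsi_trend <- rep_len(config$wsi_trend, n_cells)
  gs_trend <- rep_len(config$gs_trend, n_cells)
  y0 <- config$years[1]; y1 <- config$years[length(config$years)]
  dates <- seq(as.Date(sprintf("%d-01-01", y0)),
               as.Date(sprintf("%d-12-31", y1)), by = "day")
  lt <- as.POSIXlt(dates)
  doy <- lt$yday + 1L
  mon <- lt$mon + 1L
  yr <- lt$year + 1900L
  nd <- length(dates)
  sdn <- config$daily_noise_sd
  t_thr <- -17.7; s_thr <- 38  # winter_spec() defaults; see vignette
  res <- vector("list", n_cells)

  for (ci in seq_len(n_cells)) {
    tmean <- 1 + 14 * cos(2 * pi * (doy - 196) / 365.25) + rnorm(nd, 0, sdn)

    # growing-season plan per calendar year
    start_doy <- end_doy <- integer(y1 - y0 + 1L)
    names(start_doy) <- names(end_doy) <- as.character(y0:y1)
    for (y in y0:y1) {
      L <- config$gs_base + gs_trend[ci] * (y - y0) + rnorm(1, 0, config$gs_sd)
      s <- config$gs_start_doy + round(rnorm(1, 0, 2))
      s <- min(max(s, 65L), 165L)
      e <- min(max(s + round(L), 220L), 300L)
      start_doy[as.character(y)] <- s
      end_doy[as.character(y)] <- e
    }
    s_of_day <- start_doy[as.character(yr)]
    e_of_day <- end_doy[as.character(yr)]
    pre <- doy >= 60L & doy < s_of_day
    tmean[pre] <- pmin(tmean[pre], 4)
    run <- doy >= s_of_day & doy <= s_of_day + 4L
    tmean[run] <- 6 + abs(rnorm(sum(run), 0, sdn))
    mid <- doy > s_of_day + 4L & doy < e_of_day
    tmean[mid] <- 12 + rnorm(sum(mid), 0, sdn)
    tmin <- tmean - (3 + abs(rnorm(nd, 0, 1)))
    frostfree <- doy >= 210L & doy < e_of_day
    tmin[frostfree] <- pmax(tmin[frostfree], 0)
    endd <- doy == e_of_day
    tmin[endd] <- -3 - abs(rnorm(sum(endd), 0, 1))
    tmean[endd] <- tmin[endd] + 5

    # baseline snow course: peaks around Feb 1, stays under threshold
    feb_dist <- pmin(abs(doy - 32L), 365L - abs(doy - 32L))
    snow <- pmax(0, config$snow_peak_cm * (1 - feb_dist / 85) +
                   rnorm(nd, 0, 1.5))
    snow <- pmin(snow, s_thr - 2)

    # winter plan: plant qualifying days per winter year
    in_window <- mon >= 11L | mon <= 4L
    tmin[in_window] <- pmax(tmin[in_window], t_thr + 2)
    tmean[in_window] <- pmax(tmean[in_window], tmin[in_window])
    for (w in y0:(y1 - 1L)) {
      from <- as.Date(sprintf("%d-11-01", w))
      to <- as.Date(sprintf("%d-04-30", w + 1L))
      widx <- which(dates >= from & dates <= to)
      wlen <- length(widx)
      target <- config$wsi_base + wsi_trend[ci] * (w - y0) +
        rnorm(1, 0, config$wsi_sd)
      nq <- min(max(round(target), 0L), wlen)
      if (nq == 0L) next
      qual <- if (nq == wlen) widx else sample(widx, nq)
      # cold days only where they cannot collide with the onset run
      feb_end <- as.Date(sprintf("%d-03-01", w + 1L)) - 1L
      elig <- qual[dates[qual] <= feb_end]
      inelig <- setdiff(qual, elig)
      type <- if (length(elig))
        sample(c("cold", "snow", "both"), length(elig), replace = TRUE,
               prob = c(0.5, 0.3, 0.2)) else character()
      cold <- c(elig[type != "snow"])
      snowy <- c(elig[type != "cold"], inelig)
      if (length(cold)) {
        tmin[cold] <- t_thr - 3 - abs(rnorm(length(cold), 0, sdn))
        tmean[cold] <- tmin[cold] + 2 + abs(rnorm(length(cold), 0, 1))
      }
      if (length(snowy))
        snow[snowy] <- s_thr + 8 + abs(rnorm(length(snowy), 0, 4))
    }
    tmin <- pmin(tmin, tmean)
    res[[ci]] <- data.frame(cell_id = grid$cell_id[ci], date = dates,
                            tmin = tmin, tmean = tmean, snow_cm = snow)
  }
  do.call(rbind, res)
}

#' Generate clustered land-use event histories
#'
#' Simulates well-pad points (exponentially growing annual counts,
#' cumulative on the landscape), forestry cut blocks (a fraction with
#' unknown cut year), and agricultural census epochs occupying the
#' southern rows of the grid. New wells and cuts are placed next to one
#' of a small set of development nuclei with probability
#' `landuse_clustering` (offset by one cell at random), otherwise
#' uniformly, reproducing spatially patchy footprint growth.
#'
#' @param config a [synthetic_config()].
#' @return List of class `landuse_events` with data frames `wells`
#'   (`cell_id`, `year`, `area_km2`), `cutblocks` (`cell_id`, `year`
#'   (`NA` when unknown), `area_km2`) and `agriculture` (`cell_id`,
#'   `epoch_year`, `area_km2`).
#' @export
generate_landuse_history <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed + 1L)
  grid <- config_grid(config)
  rows <- config$grid_rows; cols <- config$grid_cols
  nuclei <- grid[sample.int(nrow(grid), min(config$n_nuclei, nrow(grid))), ]

  place <- function(n) {
    if (n == 0L) return(integer())
    clustered <- runif(n) < config$landuse_clustering
    out <- integer(n)
    if (any(clustered)) {
      k <- sample.int(nrow(nuclei), sum(clustered), replace = TRUE)
      r <- pmin(pmax(nuclei$row[k] + sample(-1:1, sum(clustered), TRUE), 1L),
                rows)
      cc <- pmin(pmax(nuclei$col[k] + sample(-1:1, sum(clustered), TRUE), 1L),
                 cols)
      out[clustered] <- (r - 1L) * cols + cc
    }
    if (any(!clustered))
      out[!clustered] <- sample.int(nrow(grid), sum(!clustered),
                                    replace = TRUE)
    out
  }

  years <- config$years
  wells <- cuts <- list()
  for (i in seq_along(years)) {
    y <- years[i]
    nw <- rpois(1, config$wells_per_year * (1 + config$wells_growth)^(i - 1))
    if (nw > 0)
      wells[[length(wells) + 1L]] <- data.frame(
        cell_id = place(nw), year = y, area_km2 = config$well_area_km2)
    nc <- rpois(1, config$cuts_per_year)
    if (nc > 0)
      cuts[[length(cuts) + 1L]] <- data.frame(
        cell_id = place(nc), year = y, area_km2 = config$cut_area_km2)
  }
  empty <- data.frame(cell_id = integer(), year = integer(),
                      area_km2 = numeric())
  wells <- if (length(wells)) do.call(rbind, wells) else empty
  cuts <- if (length(cuts)) do.call(rbind, cuts) else empty
  if (nrow(cuts) && config$cut_undated_frac > 0) {
    k <- runif(nrow(cuts)) < config$cut_undated_frac
    cuts$year[k] <- NA_integer_
  }

  agri <- list()
  for (i in seq_along(config$agri_epochs)) {
    zone_rows <- rows - seq_len(max(0L, round(config$agri_frac[i] * rows))) + 1L
    cells <- grid$cell_id[grid$row %in% zone_rows]
    if (length(cells))
      agri[[length(agri) + 1L]] <- data.frame(
        cell_id = cells, epoch_year = config$agri_epochs[i],
        area_km2 = config$agri_cover_frac * config$cell_area_km2)
  }
  agri <- if (length(agri)) do.call(rbind, agri) else
    data.frame(cell_id = integer(), epoch_year = integer(),
               area_km2 = numeric())
  out <- list(wells = wells, cutblocks = cuts, agriculture = agri)
  class(out) <- c("landuse_events", "list")
  out
}

#' Generate static land-cover proportion layers
#'
#' Per-cell proportions of deciduous forest and wetland, drawn from beta
#' distributions matched to the covariate ranges of the boreal setting
#' (deciduous mean near 0.24, wetland a few percent).
#'
#' @param config a [synthetic_config()].
#' @return Data frame `cell_id`, `prop_deciduous`, `prop_wetland`.
#' @export
generate_landcover <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed + 2L)
  grid <- config_grid(config)
  n <- nrow(grid)
  dec <- rbeta(n, 2, 6)          # mean 0.25
  wet <- rbeta(n, 1, 14) * 0.6   # mean ~0.04, max well under 0.6
  keep <- dec + wet > 0.95       # keep headroom for footprint overlay
  wet[keep] <- pmax(0, 0.95 - dec[keep])
  data.frame(cell_id = grid$cell_id, prop_deciduous = dec,
             prop_wetland = wet)
}

#' Sample presence/absence observations from a prediction grid
#'
#' Draws `n_sites` distinct cells (without replacement) and samples
#' presence as Bernoulli with probability `p * detection_prob`,
#' emulating surveys with optional imperfect detection.
#'
#' @param prediction a `prediction_grid` (columns `cell_id`, `p`).
#' @param n_sites number of sites to sample (<= number of cells).
#' @param detection_prob detection probability in `[0, 1]`.
#' @param seed integer seed.
#' @return Data frame `cell_id`, `presence` (logical).
#' @export
sample_observations <- function(prediction, n_sites, detection_prob = 1,
                                seed = 1L) {
  check_columns(prediction, c("cell_id", "p"), "prediction")
  n_sites <- check_count(n_sites, "n_sites")
  if (n_sites > nrow(prediction))
    stopf("sample_observations: n_sites (%d) exceeds number of cells (%d)",
          n_sites, nrow(prediction))
  check_prob(detection_prob, "detection_prob")
  if (any(prediction$p < 0 | prediction$p > 1))
    stopf("sample_observations: probabilities outside [0, 1]")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  idx <- sample.int(nrow(prediction), n_sites)
  p <- prediction$p[idx] * detection_prob
  data.frame(cell_id = prediction$cell_id[idx],
             presence = runif(n_sites) < p)
}
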