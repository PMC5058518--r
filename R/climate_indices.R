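#' Winter definition for the winter severity index
#'
#' The winter severity index (WSI) counts days in the November--April
#' window whose minimum temperature falls below `temp_threshold_c` and/or
#' whose snow depth exceeds `snow_threshold_cm`. The defaults are the
#' DelGiudice-style constants used by the deer distribution model:
#' -17.7 degrees C and 38 cm. Comparisons are strict (`<` and `>`); a day
#' meeting both criteria counts once. The snow criterion operates on snow
#' depth in cm as supplied by the data layer; any snow-water-equivalent
#' conversion belongs to input preparation, with the threshold kept
#' configurable here.
#'
#' @param temp_threshold_c minimum-temperature threshold in degrees C
#'   (strictly below counts).
#' @param snow_threshold_cm snow-depth threshold in cm (strictly above
#'   counts).
#' @return An object of class `winter_spec`.
#' @export
winter_spec <- function(temp_threshold_c = -17.7, snow_threshold_cm = 38) {
  check_number(temp_threshold_c, "temp_threshold_c")
  check_number(snow_threshold_cm, "snow_threshold_cm", lower = 0)
  structure(list(temp_threshold_c = temp_threshold_c,
                 snow_threshold_cm = snow_threshold_cm),
            class = "winter_spec")
}

# coerce/validate a single-cell daily series
as_daily_series <- function(series) {
  check_columns(series, c("date", "tmin", "tmean", "snow_cm"), "series")
  series$date <- as.Date(series$date)
  if (anyNA(series$date)) stopf("`series$date` contains unparseable dates")
  series[order(series$date), , drop = FALSE]
}

#' Winter severity index for one winter
#'
#' Counts the days between November 1 of `winter_year` and April 30 of
#' `winter_year + 1` (inclusive; a "winter year" is labeled by its
#' November) with minimum temperature below the temperature threshold
#' and/or snow depth above the snow threshold. The window length is 181 or
#' 182 days depending on whether the spring year is a leap year, so the
#' index is an integer in `[0, 182]`.
#'
#' Missing days inside the window are an error listing the gaps; no
#' silent imputation is performed.
#'
#' @param series single-cell daily data frame with columns `date`, `tmin`,
#'   `tmean`, `snow_cm`.
#' @param winter_year calendar year of the window's November.
#' @param spec a [winter_spec()].
#' @return Integer count of qualifying days.
#' @examples
#' d <- seq(as.Date("1980-11-01"), as.Date("1981-04-30"), by = "day")
#' s <- data.frame(date = d, tmin = -30, tmean = -25, snow_cm = 50)
#' compute_wsi(s, 1980) # 181: every day qualifies
#' @export
compute_wsi <- function(series, winter_year, spec = winter_spec()) {
  series <- as_daily_series(series)
  winter_year <- check_count(winter_year, "winter_year", lower = 0L)
  stopifnot(inherits(spec, "winter_spec"))
  from <- as.Date(sprintf("%d-11-01", winter_year))
  to <- as.Date(sprintf("%d-04-30", winter_year + 1L))
  check_window_coverage(series$date, from, to, "compute_wsi")
  win <- series[series$date >= from & series$date <= to, ]
  qual <- win$tmin < spec$temp_threshold_c |
    win$snow_cm > spec$snow_threshold_cm
  if (anyNA(qual)) stopf("compute_wsi: NA tmin/snow_cm inside the window")
  sum(qual)
}

#' Growing season length for one calendar year
#'
#' The growing season starts on the first day of the first run of at
#' least `run_days` consecutive days (searched from March 1) with mean
#' daily temperature at or above `start_temp_c`, and ends on the first
#' day strictly after August 1 whose minimum temperature reaches
#' `end_temp_c` (i.e. `tmin <= end_temp_c`). Length is `end - start` in
#' whole days (end exclusive); 0 if no qualifying run starts, and the end
#' falls back to December 31 if no qualifying cold day occurs. These
#' start/end conventions are configurable because the defining text of
#' the metric leaves them open.
#'
#' @param series single-cell daily data frame covering March 1 through
#'   December 31 of `year`.
#' @param year calendar year.
#' @param start_temp_c onset threshold for mean temperature (inclusive,
#'   default 5).
#' @param end_temp_c end threshold for minimum temperature (inclusive,
#'   default -2).
#' @param run_days length of the qualifying onset run (default 5).
#' @return Integer number of days.
#' @export
compute_growing_season <- function(series, year, start_temp_c = 5,
                                   end_temp_c = -2, run_days = 5L) {
  series <- as_daily_series(series)
  year <- check_count(year, "year", lower = 0L)
  run_days <- check_count(run_days, "run_days")
  from <- as.Date(sprintf("%d-03-01", year))
  to <- as.Date(sprintf("%d-12-31", year))
  check_window_coverage(series$date, from, to, "compute_growing_season")
  win <- series[series$date >= from & series$date <= to, ]
  if (anyNA(win$tmean) || anyNA(win$tmin))
    stopf("compute_growing_season: NA tmean/tmin inside the window")

  warm <- win$tmean >= start_temp_c
  r <- rle(warm)
  run_start_idx <- cumsum(c(1L, r$lengths))[seq_along(r$lengths)]
  ok <- r$values & r$lengths >= run_days
  if (!any(ok)) return(0L)
  start <- win$date[run_start_idx[which(ok)[1L]]]

  aug1 <- as.Date(sprintf("%d-08-01", year))
  cold <- win$date > aug1 & win$tmin <= end_temp_c
  end <- if (any(cold)) win$date[which(cold)[1L]] else to
  max(0L, as.integer(end - start))
}

#' Annual winter severity index per cell
#'
#' Computes [compute_wsi()] for every winter year whose full
#' November--April window is covered by the series, for each cell of a
#' long-format climate table.
#'
#' @param climate data frame with columns `cell_id`, `date`, `tmin`,
#'   `tmean`, `snow_cm`.
#' @param spec a [winter_spec()].
#' @return Data frame `cell_id`, `year` (November year), `value`.
#' @export
annual_wsi <- function(climate, spec = winter_spec()) {
  check_columns(climate, c("cell_id", "date", "tmin", "snow_cm"), "climate")
  climate$date <- as.Date(climate$date)
  lt <- as.POSIXlt(climate$date)
  mon <- lt$mon + 1L
  yr <- lt$year + 1900L
  in_window <- mon >= 11L | mon <= 4L
  w <- climate[in_window, ]
  wyear <- ifelse(mon[in_window] >= 11L, yr[in_window], yr[in_window] - 1L)
  qual <- as.numeric(w$tmin < spec$temp_threshold_c |
                       w$snow_cm > spec$snow_threshold_cm)
  if (anyNA(qual)) stopf("annual_wsi: NA tmin/snow_cm inside winter windows")
  key <- paste(w$cell_id, wyear, sep = "\r")
  counts <- rowsum(cbind(qual = qual, days = 1), key)
  parts <- do.call(rbind, strsplit(rownames(counts), "\r", fixed = TRUE))
  out <- data.frame(cell_id = type.convert(parts[, 1], as.is = TRUE),
                    year = as.integer(parts[, 2]),
                    value = as.integer(counts[, "qual"]),
                    days = counts[, "days"])
  # keep only winters with the full 181/182-day window present
  full <- window_length(out$year) == out$days
  out <- out[full, c("cell_id", "year", "value")]
  out <- out[order(out$cell_id, out$year), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Nov 1 (y) .. Apr 30 (y+1), inclusive
window_length <- function(winter_year) {
  leap <- ((winter_year + 1) %% 4 == 0 & (winter_year + 1) %% 100 != 0) |
    ((winter_year + 1) %% 400 == 0)
  ifelse(leap, 182L, 181L)
}

#' Annual growing season length per cell
#'
#' @inheritParams annual_wsi
#' @inheritParams compute_growing_season
#' @return Data frame `cell_id`, `year`, `value` for every calendar year
#'   fully covering March 1 through December 31.
#' @export
annual_growing_season <- function(climate, start_temp_c = 5,
                                  end_temp_c = -2, run_days = 5L) {
  check_columns(climate, c("cell_id", "date", "tmin", "tmean"), "climate")
  climate$date <- as.Date(climate$date)
  yr <- as.POSIXlt(climate$date)$year + 1900L
  out <- list()
  for (cell in unique(climate$cell_id)) {
    sub <- climate[climate$cell_id == cell, ]
    yrs <- yr[climate$cell_id == cell]
    by_year <- split(seq_len(nrow(sub)), yrs)
    for (ynm in names(by_year)) {
      y <- as.integer(ynm)
      ysub <- sub[by_year[[ynm]], ]
      need <- seq(as.Date(sprintf("%d-03-01", y)),
                  as.Date(sprintf("%d-12-31", y)), by = "day")
      if (length(by_year[[ynm]]) < length(need) ||
          !all(need %in% ysub$date)) next
      out[[length(out) + 1L]] <- data.frame(
        cell_id = cell, year = y,
        value = compute_growing_season(ysub, y, start_temp_c, end_temp_c,
                                       run_days))
    }
  }
  if (!length(out)) return(data.frame(cell_id = integer(), year = integer(),
                                      value = integer()))
  res <- do.call(rbind, out)
  res[order(res$cell_id, res$year), , drop = FALSE]
}

#' Cumulative mean of an annual index from a base year
#'
#' Arithmetic mean of the annual values from `base_year` through
#' `end_year` inclusive, per cell. The decadal covariates of the
#' distribution model are cumulative means of this kind (winter severity
#' from 1961 and growing season from 1950, each up to the beginning of
#' the decade of interest). Any missing year in the range is an error.
#'
#' @param annual data frame `cell_id`, `year`, `value` (e.g. from
#'   [annual_wsi()]).
#' @param base_year,end_year inclusive year range.
#' @return Data frame `cell_id`, `mean`.
#' @export
cumulative_mean <- function(annual, base_year, end_year) {
  check_columns(annual, c("cell_id", "year", "value"), "annual")
  base_year <- check_count(base_year, "base_year", lower = 0L)
  end_year <- check_count(end_year, "end_year", lower = 0L)
  if (end_year < base_year) stopf("`end_year` precedes `base_year`")
  years <- base_year:end_year
  sub <- annual[annual$year %in% years, ]
  counts <- table(sub$cell_id)
  bad <- names(counts)[counts != length(years)]
  missing_cells <- setdiff(unique(annual$cell_id), unique(sub$cell_id))
  if (length(bad) || length(missing_cells))
    stopf("cumulative_mean: missing years in %d..%d for cell(s): %s",
          base_year, end_year,
          paste(head(c(bad, missing_cells), 10L), collapse = ", "))
  agg <- rowsum(sub$value, sub$cell_id) / length(years)
  data.frame(cell_id = type.convert(rownames(agg), as.is = TRUE),
             mean = as.vector(agg))
}

#' Per-cell linear trend of an annual index
#'
#' Ordinary least squares of value on year, per cell. The intercept is
#' reported at `reference_year` (default: the first year present for the
#' cell), so `extrapolate_trend()` evaluates
#' `intercept + slope * (target - reference_year)`.
#'
#' @param annual data frame `cell_id`, `year`, `value`.
#' @param reference_year year at which the intercept is reported; default
#'   is each cell's first year.
#' @return Data frame `cell_id`, `slope`, `intercept`, `reference_year`
#'   of class `trend_model`.
#' @export
fit_trend <- function(annual, reference_year = NULL) {
  check_columns(annual, c("cell_id", "year", "value"), "annual")
  cells <- unique(annual$cell_id)
  out <- lapply(cells, function(cell) {
    sub <- annual[annual$cell_id == cell, ]
    if (nrow(sub) < 3L)
      stopf("fit_trend: cell %s has %d year(s); need >= 3", cell, nrow(sub))
    x <- sub$year; y <- sub$value
    ref <- reference_year %||% min(x)
    sxx <- sum((x - mean(x))^2)
    if (sxx == 0) stopf("fit_trend: cell %s has a single distinct year", cell)
    slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
    intercept <- mean(y) + slope * (ref - mean(x))
    data.frame(cell_id = cell, slope = slope, intercept = intercept,
               reference_year = ref)
  })
  res <- do.call(rbind, out)
  class(res) <- c("trend_model", class(res))
  res
}

#' Evaluate a fitted trend at a target year
#'
#' Linear extrapolation with physical bounds: values are floored at
#' `floor` (0 by default; a day count or index cannot be negative) and
#' capped at `cap` (e.g. 366 for growing season length).
#'
#' @param trend a `trend_model` from [fit_trend()].
#' @param target_year year at which to evaluate.
#' @param floor,cap bounds applied to the extrapolated value.
#' @return Data frame `cell_id`, `value`.
#' @export
extrapolate_trend <- function(trend, target_year, floor = 0, cap = Inf) {
  check_columns(trend, c("cell_id", "slope", "intercept", "reference_year"),
                "trend")
  v <- trend$intercept + trend$slope * (target_year - trend$reference_year)
  data.frame(cell_id = trend$cell_id, value = pmin(pmax(v, floor), cap))
}
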