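#' Read a pipeline run configuration
#'
#' A run configuration is a YAML (or plain list) with two blocks:
#' `synthetic` (passed to [synthetic_config()]) and `run` (decades,
#' presence threshold, validation sampling, forecast horizon). Missing
#' entries fall back to defaults.
#'
#' @param x path to a YAML file, or a list.
#' @return List of class `run_config` with elements `synthetic`
#'   (a `synthetic_config`) and `run`.
#' @export
read_run_config <- function(x) {
  if (is.character(x) && !file.exists(x))
    stopf("run config file not found: %s", x)
  cfg <- if (is.character(x)) yaml::read_yaml(x) else x
  if (!is.list(cfg)) stopf("run config must be a list or YAML path")
  run_defaults <- list(
    decades = c(1970L, 1980L, 1990L, 2000L),
    threshold = 0.73,
    wsi_base_year = 1961L, gs_base_year = 1950L,
    include_undated_cuts = TRUE, cut_age_years = 30L,
    n_validation_sites = 30L,
    forecast_decades = c(2010L, 2020L, 2030L, 2040L, 2050L))
  run <- modifyList(run_defaults, cfg$run %||% list())
  syn_args <- cfg$synthetic %||% list()
  # YAML convenience: a two-element `years` is an inclusive from/to range
  if (!is.null(syn_args$years) && length(syn_args$years) == 2L)
    syn_args$years <- seq(syn_args$years[1], syn_args$years[2])
  syn <- do.call(synthetic_config, syn_args)
  if (run$threshold <= 0 || run$threshold >= 1)
    stopf("run config: `threshold` must be in (0, 1)")
  out <- list(synthetic = syn, run = run)
  class(out) <- "run_config"
  out
}

#' Run pipeline stages to an output directory
#'
#' Orchestrates the analysis end to end on synthetic inputs: `simulate`
#' (climate, land-use events, land cover), `indices` (annual winter
#' severity and growing season), `landscape` (decadal covariate tables),
#' `hindcast` (probability and presence layers per decade), `attribute`
#' (driver labels between consecutive decades), `validate` (accuracy
#' statistics against observations sampled from the most recent decade),
#' and `forecast` (future decades under extrapolated climate with land
#' use frozen). Later stages recompute what they need from earlier
#' in-memory results, so any prefix of the stage list can be run.
#'
#' Each stage writes delimited tables (and matrix rasters for the
#' probability layers) under `out_dir`, plus a `manifest.json` recording
#' the configuration hash, seed and package version; a rerun with the
#' same configuration is bit-identical for every deterministic stage.
#'
#' @param config a `run_config`, a list, or a YAML path (see
#'   [read_run_config()]).
#' @param stages character vector of stages to run, in order.
#' @param out_dir output directory (created if needed).
#' @param seed optional integer overriding the configured seed.
#' @return Invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "indices", "landscape",
                                    "hindcast", "attribute", "validate",
                                    "forecast"),
                         out_dir, seed = NULL) {
  if (!inherits(config, "run_config")) config <- read_run_config(config)
  stages <- match.arg(stages, several.ok = TRUE)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if (!is.null(seed)) config$synthetic$seed <- check_count(seed, "seed", 0L)
  syn <- config$synthetic
  run <- config$run
  grid <- config_grid(syn)
  coefs <- sdm_coefficients()
  res <- list(grid = grid)
  outfile <- function(...) file.path(out_dir, paste0(...))
  wcsv <- function(df, name) write.csv(df, outfile(name, ".csv"),
                                       row.names = FALSE)

  # every stage needs the simulated inputs; only `simulate` writes them
  res$climate <- generate_climate(syn)
  res$events <- generate_landuse_history(syn)
  res$landcover <- generate_landcover(syn)
  if ("simulate" %in% stages) {
    wcsv(res$climate, "climate")
    wcsv(res$events$wells, "wells")
    wcsv(res$events$cutblocks, "cutblocks")
    wcsv(res$events$agriculture, "agriculture")
    wcsv(res$landcover, "landcover")
  }

  need_indices <- any(c("indices", "landscape", "hindcast", "attribute",
                        "validate", "forecast") %in% stages)
  if (need_indices) {
    res$wsi_annual <- annual_wsi(res$climate)
    res$gs_annual <- annual_growing_season(res$climate)
    if ("indices" %in% stages) {
      wcsv(res$wsi_annual, "wsi_annual")
      wcsv(res$gs_annual, "gs_annual")
    }
  }

  need_land <- any(c("landscape", "hindcast", "attribute", "validate",
                     "forecast") %in% stages)
  if (need_land) {
    res$landscapes <- lapply(run$decades, function(d)
      assemble_landscape(grid, res$events, res$landcover, res$wsi_annual,
                         res$gs_annual, d,
                         wsi_base_year = run$wsi_base_year,
                         gs_base_year = run$gs_base_year,
                         include_undated_cuts = run$include_undated_cuts,
                         cut_age_years = run$cut_age_years))
    names(res$landscapes) <- run$decades
    if ("landscape" %in% stages)
      for (d in names(res$landscapes))
        wcsv(res$landscapes[[d]], paste0("landscape_", d))
  }

  need_pred <- any(c("hindcast", "attribute", "validate", "forecast")
                   %in% stages)
  if (need_pred) {
    res$predictions <- lapply(res$landscapes, predict_probability,
                              coef = coefs)
    res$presence <- lapply(res$predictions, classify_presence,
                           threshold = run$threshold)
    if ("hindcast" %in% stages)
      for (d in names(res$predictions)) {
        wcsv(res$predictions[[d]], paste0("probability_", d))
        write_grid_matrix(res$predictions[[d]]$p, grid,
                          outfile("probability_", d, ".mat"),
                          name = paste0("probability_", d))
        wcsv(res$presence[[d]], paste0("presence_", d))
      }
  }

  if ("attribute" %in% stages) {
    res$attribution <- list()
    for (i in seq_along(run$decades)[-1]) {
      from <- as.character(run$decades[i - 1L])
      to <- as.character(run$decades[i])
      ag <- attribute_change(res$landscapes[[from]], res$landscapes[[to]],
                             coefs, run$threshold)
      nm <- paste0(from, "_", to)
      res$attribution[[nm]] <- ag
      wcsv(ag, paste0("attribution_", nm))
      summ <- summarize_attribution(ag)
      jsonlite::write_json(unclass(summ), outfile("attribution_", nm,
                                                  "_summary.json"),
                           auto_unbox = TRUE, digits = NA, null = "null")
    }
  }

  if ("validate" %in% stages) {
    last <- as.character(run$decades[length(run$decades)])
    obs <- sample_observations(res$predictions[[last]],
                               min(run$n_validation_sites, nrow(grid)),
                               syn$detection_prob, seed = syn$seed + 3L)
    p <- res$predictions[[last]]$p[match(obs$cell_id,
                                         res$predictions[[last]]$cell_id)]
    res$validation <- validation_stats(obs$presence, p, run$threshold,
                                       seed = syn$seed + 4L,
                                       label = paste0("decade_", last))
    wcsv(res$validation, "validation_stats")
  }

  if ("forecast" %in% stages) {
    base <- as.character(run$decades[length(run$decades)])
    scen <- forecast_scenario(res$landscapes[[base]], res$wsi_annual,
                              res$gs_annual,
                              wsi_base_year = run$wsi_base_year,
                              gs_base_year = run$gs_base_year)
    res$forecasts <- lapply(run$forecast_decades, function(d)
      forecast_decade(scen, d, coefs, run$threshold))
    names(res$forecasts) <- run$forecast_decades
    changes <- lapply(names(res$forecasts), function(d) {
      rc <- range_change(res$presence[[base]], res$forecasts[[d]]$presence,
                         syn$cell_area_km2)
      data.frame(decade = as.integer(d), gained_km2 = rc$gained_km2,
                 lost_km2 = rc$lost_km2, net_km2 = rc$net_km2)
    })
    res$range_change <- do.call(rbind, changes)
    for (d in names(res$forecasts))
      wcsv(res$forecasts[[d]]$prediction, paste0("forecast_probability_", d))
    wcsv(res$range_change, "range_change")
  }

  manifest <- list(
    package = "sdmdrivers",
    version = as.character(packageVersion("sdmdrivers")),
    config_hash = rlang::hash(list(synthetic = unclass(syn), run = run)),
    seed = syn$seed,
    stages = stages)
  jsonlite::write_json(manifest, outfile("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(res)
}
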