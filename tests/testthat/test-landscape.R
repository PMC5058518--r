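empty_events <- function() {
  e <- data.frame(cell_id = integer(), year = integer(),
                  area_km2 = numeric())
  list(wells = e, cutblocks = e,
       agriculture = data.frame(cell_id = integer(), epoch_year = integer(),
                                area_km2 = numeric()))
}

test_that("footprint composites wells, cuts and agriculture per decade", {
  g <- make_grid(2, 2, 10)
  ev <- empty_events()
  expect_equal(footprint_for_decade(ev, g, 1980)$prop_footprint,
               rep(0, 4))

  # additivity in one cell: well 0.5 + current cut 2.0 over area 10
  ev$wells <- data.frame(cell_id = 1L, year = 1975, area_km2 = 0.5)
  ev$cutblocks <- data.frame(cell_id = 1L, year = 1982, area_km2 = 2)
  fp <- footprint_for_decade(ev, g, 1980)
  expect_equal(fp$prop_footprint, c(0.25, 0, 0, 0))

  # wells are cumulative; a 1965 cut is aged out of the 2000s footprint
  ev$cutblocks <- data.frame(cell_id = 1L, year = 1965, area_km2 = 2)
  fp2000 <- footprint_for_decade(ev, g, 2000)
  expect_equal(fp2000$prop_footprint, c(0.05, 0, 0, 0))
  # but a 1970 cut still counts in the 2000s (30-year age from the label)
  ev$cutblocks$year <- 1970
  expect_equal(footprint_for_decade(ev, g, 2000)$prop_footprint[1], 0.25)

  # undated cuts enter iff the flag is on, and never reduce the footprint
  ev$cutblocks <- data.frame(cell_id = c(1L, 2L), year = c(1978L, NA),
                             area_km2 = 2)
  on <- footprint_for_decade(ev, g, 1980, include_undated_cuts = TRUE)
  off <- footprint_for_decade(ev, g, 1980, include_undated_cuts = FALSE)
  expect_true(all(on$prop_footprint >= off$prop_footprint))
  expect_equal(on$prop_footprint[2], 0.2)
  expect_equal(off$prop_footprint[2], 0)
})

test_that("agriculture epochs map to decades and persist once developed", {
  g <- make_grid(2, 2, 10)
  ev <- empty_events()
  ev$agriculture <- data.frame(cell_id = c(1L, 1L, 2L),
                               epoch_year = c(1991L, 2006L, 2006L),
                               area_km2 = c(4, 8, 8))
  # 1970s and 1980s use the 1991 epoch (earliest at/after the decade end)
  expect_equal(footprint_for_decade(ev, g, 1970)$prop_footprint,
               c(0.4, 0, 0, 0))
  expect_equal(footprint_for_decade(ev, g, 1980)$prop_footprint,
               c(0.4, 0, 0, 0))
  # 1990s and 2000s use the 2006 epoch, unioned with 1991 per cell
  expect_equal(footprint_for_decade(ev, g, 1990)$prop_footprint,
               c(0.8, 0.8, 0, 0))
  expect_equal(footprint_for_decade(ev, g, 2000)$prop_footprint,
               c(0.8, 0.8, 0, 0))
  # explicit epoch override
  expect_equal(footprint_for_decade(ev, g, 2000,
                                    agri_epoch = 1991)$prop_footprint,
               c(0.4, 0, 0, 0))
})

test_that("footprint is monotone over decades for wells and agriculture", {
  cfg <- synthetic_config(grid_rows = 4, grid_cols = 4, years = 1950:2009,
                          seed = 3)
  ev <- generate_landuse_history(cfg)
  ev$cutblocks <- ev$cutblocks[0, ]  # cuts may age out; exclude them here
  g <- config_grid(cfg)
  fps <- sapply(c(1970, 1980, 1990, 2000), function(d)
    footprint_for_decade(ev, g, d)$prop_footprint)
  expect_true(all(diff(t(fps)) >= -1e-12))
})

test_that("land-cover reconciliation reduces covers proportionally", {
  # excess 0.1 split 0.4:(0.4+0.2) vs 0.2:(0.4+0.2)
  adj <- reconcile_landcover(0.5, 0.4, 0.2)
  expect_equal(adj$prop_deciduous, 1 / 3, tolerance = 1e-12)
  expect_equal(adj$prop_wetland, 1 / 6, tolerance = 1e-12)
  # at or below one: unchanged
  expect_equal(reconcile_landcover(0.5, 0.3, 0.2),
               data.frame(prop_deciduous = 0.3, prop_wetland = 0.2))
  # full development erases cover
  adj2 <- reconcile_landcover(1, 0.4, 0.2)
  expect_equal(adj2$prop_deciduous, 0)
  expect_equal(adj2$prop_wetland, 0)
  expect_error(reconcile_landcover(1.2, 0, 0), "exceeds 1")

  # conservation: footprint + adjusted covers = min(1, original sum)
  set.seed(8)
  for (i in 1:50) {
    fp <- runif(1); dec <- runif(1); wet <- runif(1)
    adj <- reconcile_landcover(fp, dec, wet)
    expect_equal(fp + adj$prop_deciduous + adj$prop_wetland,
                 min(1, fp + dec + wet), tolerance = 1e-12)
  }
})

test_that("assembled landscape equals a componentwise hand assembly", {
  g <- make_grid(1, 2, 10)
  ev <- empty_events()
  ev$wells <- data.frame(cell_id = 1L, year = 1968, area_km2 = 1)
  lc <- data.frame(cell_id = 1:2, prop_deciduous = c(0.95, 0.3),
                   prop_wetland = c(0.1, 0.05))
  wsi <- expand.grid(cell_id = 1:2, year = 1961:1970)
  wsi$value <- 100 + wsi$cell_id * 10 + (wsi$year - 1961)
  gs <- expand.grid(cell_id = 1:2, year = 1950:1970)
  gs$value <- 150 + gs$cell_id
  land <- assemble_landscape(g, ev, lc, wsi, gs, 1970)

  expect_equal(land$prop_footprint, c(0.1, 0))
  # cell 1: 0.1 + 0.95 + 0.1 exceeds one; covers shrink proportionally
  hand <- reconcile_landcover(0.1, 0.95, 0.1)
  expect_equal(land$prop_deciduous, c(hand$prop_deciduous, 0.3))
  expect_equal(land$prop_wetland, c(hand$prop_wetland, 0.05))
  expect_equal(land$wsi_mean,
               c(mean(100 + 10 + 0:9), mean(100 + 20 + 0:9)))
  expect_equal(land$gs_mean, c(151, 152))
  expect_identical(attr(land, "decade"), 1970L)
  # landscape invariant after reconciliation
  expect_true(all(land$prop_footprint + land$prop_deciduous +
                    land$prop_wetland <= 1 + 1e-9))

  # no events between two decades: footprint unchanged
  wsi2 <- expand.grid(cell_id = 1:2, year = 1961:1980)
  wsi2$value <- 100
  gs2 <- expand.grid(cell_id = 1:2, year = 1950:1980)
  gs2$value <- 150
  l70 <- assemble_landscape(g, ev, lc, wsi2, gs2, 1970)
  l80 <- assemble_landscape(g, ev, lc, wsi2, gs2, 1980)
  expect_equal(l70$prop_footprint, l80$prop_footprint)
})

test_that("grid rasters round-trip through the delimited matrix dialect", {
  g <- make_grid(3, 4, 10)
  v <- seq_len(12) / 12
  path <- tempfile(fileext = ".mat")
  write_grid_matrix(v, g, path, name = "probability")
  back <- read_grid_matrix(path)
  expect_equal(back$values, v)
  expect_equal(back$grid$row, g$row)
  expect_equal(back$meta$value, "probability")
})
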