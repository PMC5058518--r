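#' Define a rectangular analysis grid
#'
#' Cells are indexed row-major from the northwest corner (row 1, col 1),
#' with 0-based row/column indices stored as 1-based for R convenience.
#' Cell area is carried explicitly so grids of any cell rectangle (the
#' reference analysis used 10 km x 1 km east-west cells) share one code
#' path.
#'
#' @param rows,cols number of grid rows and columns (>= 1).
#' @param cell_area_km2 area of one cell in km^2 (default 10, a
#'   10 km x 1 km cell).
#' @return A data frame with columns `cell_id`, `row`, `col`, `area_km2`.
#' @examples
#' g <- make_grid(4, 5)
#' nrow(g) # 20
#' @export
make_grid <- function(rows, cols, cell_area_km2 = 10) {
  rows <- check_count(rows, "rows")
  cols <- check_count(cols, "cols")
  check_number(cell_area_km2, "cell_area_km2", lower = 1e-12)
  data.frame(
    cell_id = seq_len(rows * cols),
    row = rep(seq_len(rows), each = cols),
    col = rep(seq_len(cols), times = rows),
    area_km2 = cell_area_km2
  )
}

#' Write a per-cell value layer as a delimited matrix raster
#'
#' The raster dialect is a plain tab-delimited matrix (row-major, origin at
#' the northwest corner) plus a JSON sidecar `<path>.json` recording rows,
#' columns, cell area and value name, so files round-trip bit-stably
#' without a geospatial stack.
#'
#' @param values numeric vector ordered by `cell_id`.
#' @param grid a grid from [make_grid()].
#' @param path output file path; the sidecar is written to `<path>.json`.
#' @param name short name for the value stored (recorded in the sidecar).
#' @return `path`, invisibly.
#' @export
write_grid_matrix <- function(values, grid, path, name = "value") {
  check_columns(grid, c("cell_id", "row", "col", "area_km2"), "grid")
  if (length(values) != nrow(grid))
    stopf("`values` length (%d) != number of cells (%d)",
          length(values), nrow(grid))
  nr <- max(grid$row); nc <- max(grid$col)
  m <- matrix(NA_real_, nr, nc)
  m[cbind(grid$row, grid$col)] <- values
  utils::write.table(m, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  sidecar <- list(rows = nr, cols = nc,
                  cell_area_km2 = grid$area_km2[1],
                  origin = "NW", order = "row-major", value = name)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a delimited matrix raster written by [write_grid_matrix()]
#'
#' @param path file path of the matrix; `<path>.json` must exist.
#' @return A list with elements `values` (vector in `cell_id` order),
#'   `grid` (reconstructed grid) and `meta` (sidecar contents).
#' @export
read_grid_matrix <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  m <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  grid <- make_grid(meta$rows, meta$cols, meta$cell_area_km2)
  list(values = as.vector(t(m)), grid = grid, meta = meta)
}
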