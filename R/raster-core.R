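#' Raster grid descriptor
#'
#' A `ts_grid` describes the georeferencing of every raster in a pipeline run:
#' the map coordinate of the top-left corner, a square cell size in projected
#' map units (meters), the lattice dimensions, a coordinate reference system
#' identifier and the nodata sentinel used on disk. Cell `(1, 1)` is the
#' top-left cell; a cell's value represents its full square footprint.
#'
#' @param origin_x,origin_y Map coordinates of the top-left corner of the
#'   top-left cell (x minimum, y maximum).
#' @param cell_size Cell edge length in map units; must be positive.
#' @param n_rows,n_cols Lattice dimensions, each at least 1.
#' @param crs_id Coordinate reference system identifier, e.g. `"EPSG:32610"`.
#'   Geographic (degree-unit) systems are rejected by the pipeline because all
#'   area thresholds are metric.
#' @param nodata Sentinel value used for missing cells when writing to disk.
#'   In memory, missing cells are always `NA`.
#' @return An object of class `ts_grid`.
#' @export
ts_grid <- function(origin_x, origin_y, cell_size, n_rows, n_cols,
                    crs_id = "EPSG:32610", nodata = -9999) {
  stopifnot(is.numeric(origin_x), is.numeric(origin_y),
            is.numeric(cell_size), length(cell_size) == 1L, cell_size > 0,
            n_rows >= 1, n_cols >= 1)
  structure(list(origin_x = as.numeric(origin_x),
                 origin_y = as.numeric(origin_y),
                 cell_size = as.numeric(cell_size),
                 n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 crs_id = as.character(crs_id),
                 nodata = as.numeric(nodata)),
            class = "ts_grid")
}

#' @export
print.ts_grid <- function(x, ...) {
  cat(sprintf("<ts_grid> %d x %d cells @ %g m, origin (%g, %g), %s\n",
              x$n_rows, x$n_cols, x$cell_size, x$origin_x, x$origin_y,
              x$crs_id))
  invisible(x)
}

# EPSG codes of common geographic (degree-unit) systems; the pipeline refuses
# them because hectare thresholds require projected meters.
.geographic_epsg <- c("EPSG:4326", "EPSG:4269", "EPSG:4258", "EPSG:4267")

#' Test whether a CRS identifier denotes a geographic (degree) system
#' @param crs_id CRS identifier string.
#' @return Logical.
#' @export
is_geographic_crs <- function(crs_id) {
  toupper(trimws(crs_id)) %in% .geographic_epsg
}

#' Multiband raster
#'
#' The universal raster currency of the package: a [ts_grid()] plus an ordered
#' list of named bands, each an `n_rows x n_cols` numeric matrix. Missing cells
#' are `NA`; every operation consuming an `NA` cell emits `NA`, and statistics
#' ignore `NA`.
#'
#' @param grid A [ts_grid()].
#' @param bands Named list of numeric matrices, all of dimension
#'   `n_rows x n_cols`. Band names must be unique and non-empty.
#' @return An object of class `ts_raster`.
#' @export
ts_raster <- function(grid, bands) {
  stopifnot(inherits(grid, "ts_grid"), is.list(bands), length(bands) >= 1L)
  nm <- names(bands)
  if (is.null(nm) || any(nm == "") || anyDuplicated(nm))
    stop("bands must have unique, non-empty names")
  for (b in bands) {
    if (!is.matrix(b) || !is.numeric(b))
      stop("each band must be a numeric matrix")
    if (nrow(b) != grid$n_rows || ncol(b) != grid$n_cols)
      stop(sprintf("band dimensions %d x %d do not match grid %d x %d",
                   nrow(b), ncol(b), grid$n_rows, grid$n_cols))
  }
  structure(list(grid = grid, bands = bands), class = "ts_raster")
}

#' @export
print.ts_raster <- function(x, ...) {
  cat(sprintf("<ts_raster> %d band(s) [%s] on %d x %d grid @ %g m\n",
              length(x$bands), paste(names(x$bands), collapse = ", "),
              x$grid$n_rows, x$grid$n_cols, x$grid$cell_size))
  invisible(x)
}

#' Number of bands of a raster
#' @param raster A [ts_raster()].
#' @return Integer count.
#' @export
n_bands <- function(raster) length(raster$bands)

#' Extract one band as a matrix
#' @param raster A [ts_raster()].
#' @param which Band name or integer position.
#' @return Numeric matrix.
#' @export
band <- function(raster, which) {
  b <- raster$bands[[which]]
  if (is.null(b)) stop("no band named '", which, "'")
  b
}

#' Subset bands of a raster
#' @param raster A [ts_raster()].
#' @param which Character or integer vector of bands to keep.
#' @return A [ts_raster()] with the selected bands, in the requested order.
#' @export
subset_bands <- function(raster, which) {
  ts_raster(raster$grid, raster$bands[which])
}

#' Cell-center coordinates of a grid
#'
#' @param grid A [ts_grid()].
#' @param rows,cols Optional integer vectors of equal length selecting cells;
#'   by default all cells in column-major order.
#' @return Data frame with columns `row`, `col`, `x`, `y`.
#' @export
cell_centers <- function(grid, rows = NULL, cols = NULL) {
  if (is.null(rows)) {
    rows <- rep(seq_len(grid$n_rows), times = grid$n_cols)
    cols <- rep(seq_len(grid$n_cols), each = grid$n_rows)
  }
  data.frame(row = rows, col = cols,
             x = grid$origin_x + (cols - 0.5) * grid$cell_size,
             y = grid$origin_y - (rows - 0.5) * grid$cell_size)
}

#' Convert map coordinates to (row, col) cell indices
#' @param grid A [ts_grid()].
#' @param x,y Map coordinate vectors.
#' @return Data frame with columns `row`, `col`; coordinates outside the grid
#'   give `NA`.
#' @export
map_to_cell <- function(grid, x, y) {
  col <- floor((x - grid$origin_x) / grid$cell_size) + 1L
  row <- floor((grid$origin_y - y) / grid$cell_size) + 1L
  bad <- row < 1L | row > grid$n_rows | col < 1L | col > grid$n_cols
  row[bad] <- NA_integer_; col[bad] <- NA_integer_
  data.frame(row = row, col = col)
}

#' Assert two rasters share an identical grid
#'
#' Enforces the outcome of co-registration: origin, cell size, dimensions and
#' CRS must all agree exactly. Succeeds silently, or raises an error naming the
#' first mismatching field.
#'
#' @param a,b [ts_raster()] or [ts_grid()] objects.
#' @return Invisibly `TRUE` when aligned.
#' @export
assert_same_grid <- function(a, b) {
  ga <- if (inherits(a, "ts_raster")) a$grid else a
  gb <- if (inherits(b, "ts_raster")) b$grid else b
  stopifnot(inherits(ga, "ts_grid"), inherits(gb, "ts_grid"))
  for (f in c("origin_x", "origin_y", "cell_size", "n_rows", "n_cols",
              "crs_id")) {
    if (!identical(as.vector(ga[[f]]), as.vector(gb[[f]])))
      stop(sprintf("grid mismatch in field '%s': %s vs %s", f,
                   format(ga[[f]]), format(gb[[f]])), call. = FALSE)
  }
  invisible(TRUE)
}

#' Area of one grid cell in hectares
#' @param grid A [ts_grid()].
#' @return Numeric, `cell_size^2 / 10000`.
#' @export
cell_area_ha <- function(grid) grid$cell_size^2 / 1e4
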