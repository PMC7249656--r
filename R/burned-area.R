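# Prescribed-fire candidate polygons from per-date binary burned rasters.

#' Merge per-date binary burned rasters
#'
#' Logical OR across dates: a cell is burned (1) when any input marks it
#' burned; nodata only where every input is nodata.
#'
#' @param rasters List of one-band [ts_raster()] objects with values in
#'   `{0, 1, NA}` on one shared grid.
#' @return A one-band binary [ts_raster()] (`burned`).
#' @export
merge_burned <- function(rasters) {
  stopifnot(length(rasters) >= 1L)
  g <- rasters[[1]]$grid
  for (r in rasters) {
    assert_same_grid(rasters[[1]], r)
    vals <- r$bands[[1]][!is.na(r$bands[[1]])]
    if (!all(vals %in% c(0, 1)))
      stop("burned rasters must be binary (0/1/nodata)")
  }
  acc <- matrix(NA_real_, g$n_rows, g$n_cols)
  for (r in rasters) {
    b <- r$bands[[1]]
    acc <- ifelse(is.na(acc), b, pmax(acc, b, na.rm = TRUE))
  }
  ts_raster(g, list(burned = acc))
}

#' Extract prescribed-fire candidate polygons
#'
#' Polygonizes burned cells (8-connected), then applies the shared filtering
#' rules: drop slivers below `min_area_ha`, drop polygons intersecting any
#' wildfire perimeter, drop polygons with more than half their area over
#' non-forest. Survivors are typed `prescribed_fire`; removals are returned
#' for audit.
#'
#' @param merged A [merge_burned()] binary raster.
#' @param wildfires A [ts_polyset()] of wildfire perimeters.
#' @param forest_mask One-band binary [ts_raster()].
#' @param min_area_ha Sliver threshold (default 1 ha).
#' @return A list with [ts_polyset()] fields `kept` (typed
#'   `prescribed_fire`) and `removed`.
#' @export
prescribed_fire_polygons <- function(merged, wildfires, forest_mask,
                                     min_area_ha = 1) {
  b <- merged$bands[[1]]
  vals <- b[!is.na(b)]
  if (!all(vals %in% c(0, 1))) stop("merged raster must be binary")
  sel <- matrix(NA_real_, nrow(b), ncol(b))
  sel[!is.na(b) & b == 1] <- 1
  candidates <- threshold_polygonize(ts_raster(merged$grid,
                                               list(burn = sel)), 0.5)
  res <- filter_polygons(candidates, wildfires, forest_mask, min_area_ha)
  if (n_polygons(res$kept) > 0L)
    res$kept$attributes$type <- "prescribed_fire"
  res
}
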