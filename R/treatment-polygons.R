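# Candidate treatment polygons from segment surfaces, the filtering ledger
# (slivers, wildfire perimeters, non-forest), and the kernel-density summary.

#' Polygonize cells above a threshold
#'
#' Cells whose value exceeds the threshold (strict `>`) are grouped into
#' 8-connected components and each component becomes one polygon (the union
#' of its cell squares, holes preserved), carrying its mean value and area.
#'
#' @param segvals A one-band [ts_raster()], typically from
#'   [segment_value_raster()].
#' @param threshold Finite cutoff value.
#' @return A [ts_polyset()] with attributes `mean_vote`, `n_cells`,
#'   `area_ha`, `type = "candidate"` and `removal_reason = "none"`; empty
#'   when nothing exceeds the threshold.
#' @export
threshold_polygonize <- function(segvals, threshold) {
  stopifnot(is.finite(threshold))
  v <- segvals$bands[[1]]
  sel <- matrix(NA_real_, nrow(v), ncol(v))
  keep <- !is.na(v) & v > threshold
  sel[keep] <- 1
  if (!any(keep))
    return(ts_polyset(list(), data.frame(mean_vote = numeric(0),
                                         n_cells = integer(0),
                                         type = character(0),
                                         removal_reason = character(0))))
  lab <- label_components(sel, connectivity = 8)
  ps <- polygonize_labels(lab, segvals$grid, values = v)
  at <- data.frame(mean_vote = ps$attributes$mean_value,
                   n_cells = ps$attributes$n_cells,
                   type = "candidate", removal_reason = "none",
                   stringsAsFactors = FALSE)
  ts_polyset(ps$geometries, at)
}

#' Apply the treatment-polygon filtering rules
#'
#' In order: (1) slivers — polygons below `min_area_ha` are removed;
#' (2) wildfire overlap — any polygon whose geometry intersects (including
#' boundary touches) any wildfire perimeter of the period is removed;
#' (3) non-forest — polygons with more than half their area over non-forest
#' cells are removed. Removed polygons are retained in an audit set with
#' their `removal_reason`, so survivors plus audit always reassemble the
#' input.
#'
#' @param candidates A [threshold_polygonize()] result.
#' @param wildfires A [ts_polyset()] of wildfire perimeters (may be empty).
#' @param forest_mask One-band binary [ts_raster()] (1 = forest), or `NULL`
#'   to skip the non-forest rule.
#' @param min_area_ha Sliver threshold in hectares (default 1).
#' @param exclusions Optional user-supplied exclusion polygons (e.g. clouds,
#'   haze, snow); intersecting polygons are removed with reason `"user"`.
#' @return A list with [ts_polyset()] fields `kept` and `removed`.
#' @export
filter_polygons <- function(candidates, wildfires = NULL, forest_mask = NULL,
                            min_area_ha = 1, exclusions = NULL) {
  n <- n_polygons(candidates)
  reason <- rep("none", n)
  area <- candidates$attributes$area_ha
  reason[area < min_area_ha] <- "sliver"
  if (!is.null(wildfires) && n_polygons(wildfires) > 0L) {
    for (k in which(reason == "none")) {
      hit <- any(polyset_intersecting(wildfires,
                                      candidates$geometries[[k]]))
      if (hit) reason[k] <- "wildfire_overlap"
    }
  }
  if (!is.null(forest_mask)) {
    fm <- forest_mask$bands[[1]]
    g <- forest_mask$grid
    for (k in which(reason == "none")) {
      inb <- rasterize_polyset(subset_polyset(candidates, k), g) == 1
      if (!any(inb)) next
      nonforest <- mean(is.na(fm[inb]) | fm[inb] == 0)
      if (nonforest > 0.5) reason[k] <- "nonforest"
    }
  }
  if (!is.null(exclusions) && n_polygons(exclusions) > 0L) {
    for (k in which(reason == "none")) {
      if (any(polyset_intersecting(exclusions, candidates$geometries[[k]])))
        reason[k] <- "user"
    }
  }
  out <- candidates
  out$attributes$removal_reason <- reason
  list(kept = subset_polyset(out, reason == "none"),
       removed = subset_polyset(out, reason != "none"))
}

#' Suggest a polygonization threshold from known treatments
#'
#' The 5th percentile of segment-mean values sampled at cells inside known
#' treatment polygons: nearly all known-treatment cells sit above it, while
#' background segments fall below.
#'
#' @param segvals A [segment_value_raster()] raster.
#' @param known A [ts_polyset()] of known treatment polygons.
#' @param prob Quantile used (default 0.05).
#' @return Numeric threshold.
#' @export
suggest_threshold <- function(segvals, known, prob = 0.05) {
  if (n_polygons(known) == 0L) stop("no known treatment polygons")
  inb <- rasterize_polyset(known, segvals$grid) == 1
  vals <- segvals$bands[[1]][inb]
  vals <- vals[is.finite(vals)]
  if (length(vals) == 0L)
    stop("known polygons cover no finite segment values")
  stats::quantile(vals, prob, names = FALSE)
}

#' Kernel density of treatment occurrence
#'
#' Rasterizes the treatment polygons to a binary coarse grid, converts
#' treated cells to points at their centers, and evaluates a quartic
#' (biweight) kernel density with the given search radius:
#' `K(d) = 3 / (pi r^2) * (1 - (d/r)^2)^2` for `d < r`, which integrates to
#' one per point. Output is in points per square kilometer.
#'
#' @param treatments A [ts_polyset()] (empty input gives a zero surface).
#' @param base_grid A [ts_grid()] fixing the extent (e.g. the scene grid).
#' @param cell_size Output cell size in meters (default 100).
#' @param radius Kernel search radius in meters (default 1000).
#' @param pad Extra margin in meters around the base extent so kernel mass
#'   near the boundary is retained (default `radius`).
#' @return A one-band [ts_raster()] (`density`, points per km^2) on the
#'   coarse padded grid.
#' @export
kernel_density <- function(treatments, base_grid, cell_size = 100,
                           radius = 1000, pad = radius) {
  np <- ceiling(pad / cell_size)
  nr <- ceiling(base_grid$n_rows * base_grid$cell_size / cell_size) + 2L * np
  nc <- ceiling(base_grid$n_cols * base_grid$cell_size / cell_size) + 2L * np
  g <- ts_grid(base_grid$origin_x - np * cell_size,
               base_grid$origin_y + np * cell_size,
               cell_size, nr, nc, crs_id = base_grid$crs_id)
  dens <- matrix(0, nr, nc)
  if (n_polygons(treatments) > 0L) {
    treated <- rasterize_polyset(treatments, g) == 1
    pts <- which(treated, arr.ind = TRUE)
    xs <- g$origin_x + (seq_len(nc) - 0.5) * cell_size
    ys <- g$origin_y - (seq_len(nr) - 0.5) * cell_size
    for (i in seq_len(nrow(pts))) {
      px <- g$origin_x + (pts[i, 2] - 0.5) * cell_size
      py <- g$origin_y - (pts[i, 1] - 0.5) * cell_size
      c1 <- max(1L, ceiling((px - radius - g$origin_x) / cell_size))
      c2 <- min(nc, floor((px + radius - g$origin_x) / cell_size) + 1L)
      r1 <- max(1L, ceiling((g$origin_y - py - radius) / cell_size))
      r2 <- min(nr, floor((g$origin_y - py + radius) / cell_size) + 1L)
      dx2 <- (xs[c1:c2] - px)^2
      dy2 <- (ys[r1:r2] - py)^2
      d2 <- outer(dy2, dx2, "+")
      k <- 3 / (pi * radius^2) * pmax(1 - d2 / radius^2, 0)^2
      dens[r1:r2, c1:c2] <- dens[r1:r2, c1:c2] + k
    }
    dens <- dens * 1e6  # per m^2 -> per km^2
  }
  ts_raster(g, list(density = dens))
}
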