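# Labeled training sets: random points in forest, truth-polygon labels,
# 30/70 composition enforcement, predictor extraction.

#' Draw random candidate points inside the forest mask
#'
#' Selects `n` distinct forest cells uniformly at random and returns their
#' cell-center coordinates. Reproducible under `seed`.
#'
#' @param mask One-band binary [ts_raster()] (1 = forest).
#' @param n Number of points (default 500).
#' @param seed Integer seed.
#' @return Data frame with columns `row`, `col`, `x`, `y`.
#' @export
draw_candidate_points <- function(mask, n = 500L, seed = 1L) {
  m <- mask$bands[[1]]
  idx <- which(!is.na(m) & m == 1)
  if (length(idx) < n)
    stop("mask has only ", length(idx), " forest cells; need ", n)
  set.seed(seed)
  sel <- if (length(idx) == n) idx else sample(idx, n)
  rc <- arrayInd(sel, dim(m))
  cell_centers(mask$grid, rows = rc[, 1], cols = rc[, 2])
}

#' Label points against truth polygons
#'
#' Label 1 where the point falls inside any truth polygon (even-odd rule),
#' else 0.
#'
#' @param points Data frame with `x`, `y` columns.
#' @param truth A [ts_polyset()] of treatment truth polygons.
#' @return The points data frame with a `label` column added.
#' @export
label_points <- function(points, truth) {
  points$label <- as.integer(points_in_polyset(points$x, points$y, truth))
  points
}

#' Enforce the treatment/non-treatment training composition
#'
#' Treatments occupy a small fraction of a landscape, so a uniform random
#' sample contains few treatment points. When the treatment fraction falls
#' short of `target_ratio`, additional points are placed uniformly at random
#' on cells inside the truth polygons until the fraction is within
#' `tolerance` of the target; non-treatment points are never deleted, and a
#' sample already at or above the target is returned unchanged.
#'
#' @param points Labeled points from [label_points()].
#' @param truth A [ts_polyset()] of treatment truth polygons (non-empty when
#'   additions are needed).
#' @param grid The [ts_grid()] points live on (added points snap to cell
#'   centers so predictor extraction stays exact).
#' @param target_ratio Target treatment fraction (default 0.30).
#' @param tolerance Acceptable deviation (default 0.02, i.e. 28-32%).
#' @param seed Integer seed for the added points.
#' @return A labeled points data frame meeting the composition.
#' @export
balance_training <- function(points, truth, grid, target_ratio = 0.30,
                             tolerance = 0.02, seed = 1L) {
  n1 <- sum(points$label == 1L); n0 <- sum(points$label == 0L)
  if (n1 / (n1 + n0) >= target_ratio - tolerance) return(points)
  tr <- rasterize_polyset(truth, grid)
  cells <- which(tr == 1)
  if (length(cells) == 0L)
    stop("truth polygons contain no cells; composition unreachable")
  need <- round(n0 * target_ratio / (1 - target_ratio)) - n1
  set.seed(seed)
  sel <- if (length(cells) >= need) sample(cells, need)
         else sample(cells, need, replace = TRUE)
  rc <- arrayInd(sel, c(grid$n_rows, grid$n_cols))
  add <- cell_centers(grid, rows = rc[, 1], cols = rc[, 2])
  add$label <- 1L
  out <- rbind(points[, c("row", "col", "x", "y", "label")], add)
  frac <- mean(out$label == 1L)
  if (abs(frac - target_ratio) > tolerance)
    warning(sprintf("achieved treatment fraction %.3f outside target %.2f +/- %.2f",
                    frac, target_ratio, tolerance))
  out
}

#' Extract predictor values at point locations
#'
#' Points are cell centers, so extraction reads the containing cell exactly
#' (no interpolation). Points falling on nodata in any kept band are dropped
#' with a warning.
#'
#' @param points Labeled points data frame (`x`, `y`, `label`).
#' @param stack A [compose_predictors()] stack; only kept bands are
#'   extracted.
#' @return A data frame with `x`, `y`, `label` and one column per kept band
#'   (class `ts_training_set` attributes record the band names).
#' @export
extract_predictors <- function(points, stack) {
  g <- stack$raster$grid
  rc <- map_to_cell(g, points$x, points$y)
  if (anyNA(rc$row)) stop("some points fall outside the grid")
  kb <- kept_bands(stack)
  vals <- sapply(kb, function(bn)
    stack$raster$bands[[bn]][cbind(rc$row, rc$col)])
  vals <- matrix(vals, nrow = nrow(points),
                 dimnames = list(NULL, kb))
  ok <- rowSums(is.na(vals)) == 0L
  if (!any(ok)) stop("all points fall on nodata cells")
  if (any(!ok))
    warning(sum(!ok), " point(s) on nodata cells dropped")
  out <- cbind(points[ok, c("x", "y", "label")],
               as.data.frame(vals[ok, , drop = FALSE]))
  rownames(out) <- NULL
  attr(out, "predictor_bands") <- kb
  class(out) <- c("ts_training_set", class(out))
  out
}
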