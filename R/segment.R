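# Mean-shift segmentation of the treatment-vote band into homogeneous
# segments with a minimum size.
#
# Detail parameters follow the 1-20 convention of common GIS segmentation
# tools, where higher detail means finer output. They map to bandwidths as:
# spatial bandwidth h_s = 21 - spatial_detail cells, used as the diameter of
# the flat spatial kernel (detail 10 -> h_s = 11, window radius 5.5 cells);
# range bandwidth h_r = (21 - spectral_detail) / 20 of the band's value range
# (detail 20 -> 5% of the range). Any monotone mapping would honor the
# convention; this one is fixed so results are reproducible.

#' Mean-shift segmentation of the vote surface
#'
#' Runs flat-kernel mean-shift filtering of the treatment band in the joint
#' spatial-range domain (blurring variant: each iteration replaces a cell's
#' value by the mean of window neighbors within the range bandwidth, until
#' the largest shift falls below `1e-4` of the value range or 100
#' iterations). Filtered cells are then grouped by 8-connected component
#' labeling of cells whose values differ by less than the range bandwidth,
#' and segments smaller than `min_size` are merged iteratively into the
#' adjacent segment with the closest mean vote. Deterministic.
#'
#' @param votes A [predict_vote_raster()] result (band `treatment` is
#'   segmented), or any one/two-band [ts_raster()] (the last band is used).
#' @param spectral_detail Spectral detail on the 1-20 scale (default 20, the
#'   finest spectral discrimination).
#' @param spatial_detail Spatial detail on the 1-20 scale (default 10,
#'   moderate).
#' @param min_size Minimum segment size in cells (default 10).
#' @return An object of class `ts_segments`: `labels` (integer matrix,
#'   contiguous ids from 1, `NA` outside finite votes), `segment_means`
#'   (id-indexed mean vote), `segment_sizes` (id-indexed cell counts),
#'   `grid`, and `votes` (the segmented band).
#' @export
mean_shift_segment <- function(votes, spectral_detail = 20,
                               spatial_detail = 10, min_size = 10L) {
  stopifnot(spectral_detail >= 1, spectral_detail <= 20,
            spatial_detail >= 1, spatial_detail <= 20, min_size >= 1)
  v <- votes$bands[[length(votes$bands)]]
  g <- votes$grid
  mask <- is.finite(v)
  if (!any(mask)) stop("votes band has no finite cells")
  rng <- diff(range(v[mask]))
  if (sum(mask) < min_size) {
    warning("fewer finite cells than min_size; returning a single segment")
    lab <- matrix(NA_integer_, nrow(v), ncol(v)); lab[mask] <- 1L
    return(.segments_from_labels(lab, v, g))
  }
  h_s <- 21 - spatial_detail
  h_r <- (21 - spectral_detail) / 20 * rng
  if (h_r <= 0) h_r <- .Machine$double.eps  # degenerate constant raster
  rad <- h_s / 2
  w <- floor(rad)
  offs <- expand.grid(dr = -w:w, dc = -w:w)
  offs <- offs[offs$dr^2 + offs$dc^2 <= rad^2, ]
  tol <- 1e-4 * max(rng, .Machine$double.eps)
  cur <- v
  for (it in seq_len(100L)) {
    s <- matrix(0, nrow(v), ncol(v)); n <- s
    for (i in seq_len(nrow(offs))) {
      nb <- .shift_mat(cur, offs$dr[i], offs$dc[i])
      ok <- !is.na(nb) & abs(nb - cur) <= h_r
      nbz <- nb; nbz[!ok] <- 0
      s <- s + nbz; n <- n + ok
    }
    nxt <- s / n
    nxt[!mask] <- NA
    shift <- max(abs(nxt - cur)[mask])
    cur <- nxt
    if (shift < tol) break
  }
  # absolute tolerance floor: filtered means of equal values can differ in
  # the last ulp across neighborhood sizes
  lab <- label_components(cur, mask, tol = max(h_r, tol, 1e-9),
                          connectivity = 8)
  lab <- .merge_small_segments(lab, v, min_size)
  .segments_from_labels(lab, v, g)
}

# Merge segments below min_size into the adjacent segment with the closest
# mean vote, smallest segment first; recompute adjacency through a label map.
.merge_small_segments <- function(lab, votes, min_size) {
  ids <- sort(unique(lab[!is.na(lab)]))
  if (length(ids) <= 1L) return(lab)
  flat <- as.vector(lab)
  sums <- as.vector(tapply(as.vector(votes)[!is.na(flat)],
                           flat[!is.na(flat)], sum))
  sizes <- tabulate(flat[!is.na(flat)], nbins = max(ids))[ids]
  names(sums) <- names(sizes) <- ids
  # adjacency pairs over 8-connectivity
  pairs <- NULL
  for (i in seq_len(nrow(.offsets8))) {
    nb <- .shift_mat(lab, .offsets8[i, 1], .offsets8[i, 2])
    sel <- !is.na(lab) & !is.na(nb) & lab != nb
    if (any(sel)) pairs <- rbind(pairs, cbind(lab[sel], nb[sel]))
  }
  pairs <- unique(pairs)
  parent <- seq_len(max(ids))
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  repeat {
    roots <- vapply(ids, find, 0L)
    rsize <- tapply(sizes, roots, sum)
    rsum <- tapply(sums, roots, sum)
    small <- names(rsize)[rsize < min_size]
    if (length(small) == 0L || length(rsize) == 1L) break
    s <- as.integer(small[which.min(rsize[small])])
    members <- ids[roots == s]
    nb_roots <- unique(vapply(
      pairs[pairs[, 1] %in% members, 2], find, 0L))
    nb_roots <- setdiff(nb_roots, s)
    if (length(nb_roots) == 0L) break  # isolated by nodata: keep as is
    mean_s <- rsum[as.character(s)] / rsize[as.character(s)]
    nb_means <- rsum[as.character(nb_roots)] / rsize[as.character(nb_roots)]
    parent[s] <- nb_roots[which.min(abs(nb_means - mean_s))]
  }
  roots <- vapply(seq_len(max(ids)), function(x)
    if (x %in% ids) find(x) else NA_integer_, 0L)
  out <- lab
  out[!is.na(lab)] <- roots[lab[!is.na(lab)]]
  # renumber contiguously by first occurrence in row-major order
  order_rm <- as.vector(t(out))
  first <- unique(order_rm[!is.na(order_rm)])
  remap <- integer(max(first)); remap[first] <- seq_along(first)
  out[!is.na(out)] <- remap[out[!is.na(out)]]
  out
}

.segments_from_labels <- function(lab, votes, grid) {
  ids <- sort(unique(lab[!is.na(lab)]))
  means <- vapply(ids, function(i) mean(votes[lab == i], na.rm = TRUE), 0)
  sizes <- vapply(ids, function(i) sum(lab == i, na.rm = TRUE), 0L)
  structure(list(labels = lab,
                 segment_means = stats::setNames(means, ids),
                 segment_sizes = stats::setNames(sizes, ids),
                 grid = grid, votes = votes),
            class = "ts_segments")
}

#' @export
print.ts_segments <- function(x, ...) {
  cat(sprintf("<ts_segments> %d segment(s), sizes %d-%d cells\n",
              length(x$segment_sizes),
              min(x$segment_sizes), max(x$segment_sizes)))
  invisible(x)
}

#' Segment-mean value raster
#'
#' Replaces every cell by its segment's mean vote, producing the smoothed
#' surface whose high values correspond to likely treatments.
#'
#' @param seg A [mean_shift_segment()] result.
#' @return A one-band [ts_raster()] (`segment_value`).
#' @export
segment_value_raster <- function(seg) {
  out <- matrix(NA_real_, nrow(seg$labels), ncol(seg$labels))
  fin <- !is.na(seg$labels)
  out[fin] <- seg$segment_means[as.character(seg$labels[fin])]
  ts_raster(seg$grid, list(segment_value = out))
}
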