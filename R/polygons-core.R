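# Planar polygon sets and the raster/vector conversions the pipeline needs.
#
# A geometry is a list of closed rings (first vertex repeated last), each an
# n x 2 coordinate matrix in the grid CRS. Rings produced by polygonization
# are oriented with the region interior on the left: outer rings
# counterclockwise (positive shoelace area), holes clockwise (negative), so
# the signed ring areas of a geometry sum to its area. Containment uses the
# even-odd rule over all rings of a geometry.

#' Construct a polygon set
#'
#' @param geometries List of geometries; each geometry is a list of closed
#'   rings (`n x 2` matrices, first row equal to last row).
#' @param attributes Data frame with one row per geometry (default: empty
#'   attributes). An `area_ha` column is (re)computed from the geometry.
#' @return An object of class `ts_polyset`.
#' @export
ts_polyset <- function(geometries = list(), attributes = NULL) {
  n <- length(geometries)
  geometries <- lapply(geometries, function(g) {
    if (!is.list(g)) stop("each geometry must be a list of rings")
    lapply(g, function(r) {
      if (!is.matrix(r) || ncol(r) != 2 || nrow(r) < 4)
        stop("each ring must be an n x 2 matrix with >= 4 rows (closed)")
      if (any(abs(r[1, ] - r[nrow(r), ]) > 1e-9))
        stop("rings must be closed (first vertex == last vertex)")
      storage.mode(r) <- "double"  # integer coords overflow the shoelace
      r
    })
  })
  if (is.null(attributes)) attributes <- data.frame(row.names = seq_len(n))
  if (nrow(attributes) != n)
    stop("attributes must have one row per geometry")
  attributes$area_ha <- vapply(geometries, geom_area, 0) / 1e4
  structure(list(geometries = geometries, attributes = attributes),
            class = "ts_polyset")
}

#' @export
print.ts_polyset <- function(x, ...) {
  cat(sprintf("<ts_polyset> %d geometrie(s), %.2f ha total\n",
              length(x$geometries), sum(x$attributes$area_ha)))
  if (nrow(x$attributes)) print(utils::head(x$attributes, 10))
  invisible(x)
}

#' Number of geometries in a polygon set
#' @param ps A [ts_polyset()].
#' @return Integer count.
#' @export
n_polygons <- function(ps) length(ps$geometries)

#' Subset a polygon set by row
#' @param ps A [ts_polyset()].
#' @param idx Integer or logical index over geometries.
#' @return A [ts_polyset()].
#' @export
subset_polyset <- function(ps, idx) {
  at <- ps$attributes[idx, , drop = FALSE]
  rownames(at) <- NULL
  ts_polyset(ps$geometries[idx], at)
}

#' Bind two polygon sets
#' @param a,b [ts_polyset()] objects with compatible attribute columns.
#' @return A [ts_polyset()].
#' @export
bind_polysets <- function(a, b) {
  cols <- union(names(a$attributes), names(b$attributes))
  fill <- function(d) { for (cl in setdiff(cols, names(d))) d[[cl]] <- NA; d[cols] }
  at <- rbind(fill(a$attributes), fill(b$attributes))
  rownames(at) <- NULL
  ts_polyset(c(a$geometries, b$geometries), at)
}

.ring_signed_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- nrow(ring)
  sum(x[-n] * y[-1] - x[-1] * y[-n]) / 2
}

#' Planar area of a geometry (map units squared)
#'
#' Signed shoelace areas of all rings summed: counterclockwise outer rings
#' count positive, clockwise holes negative.
#' @param geom A geometry (list of closed rings).
#' @return Numeric area in squared map units.
#' @export
geom_area <- function(geom) sum(vapply(geom, .ring_signed_area, 0))

# Even-odd crossing count of points against a single ring; vectorized over
# points. Points exactly on an edge may land on either side (callers use cell
# centers, which never sit on cell-aligned boundaries).
.ring_crossings <- function(px, py, ring) {
  inside <- logical(length(px))
  n <- nrow(ring) - 1L
  x <- ring[, 1]; y <- ring[, 2]
  for (i in seq_len(n)) {
    x1 <- x[i]; y1 <- y[i]; x2 <- x[i + 1L]; y2 <- y[i + 1L]
    crosses <- (y1 > py) != (y2 > py)
    if (any(crosses)) {
      xin <- x1 + (py[crosses] - y1) / (y2 - y1) * (x2 - x1)
      hit <- px[crosses] < xin
      idx <- which(crosses)[hit]
      inside[idx] <- !inside[idx]
    }
  }
  inside
}

#' Even-odd containment of points in one geometry
#' @param px,py Point coordinate vectors.
#' @param geom A geometry (list of closed rings).
#' @return Logical vector.
#' @export
points_in_geom <- function(px, py, geom) {
  inside <- logical(length(px))
  for (ring in geom) inside <- xor(inside, .ring_crossings(px, py, ring))
  inside
}

#' Containment of points in any geometry of a polygon set
#' @param px,py Point coordinate vectors.
#' @param ps A [ts_polyset()].
#' @return Logical vector: `TRUE` where the point lies inside at least one
#'   geometry.
#' @export
points_in_polyset <- function(px, py, ps) {
  inside <- logical(length(px))
  for (geom in ps$geometries) {
    todo <- !inside
    if (!any(todo)) break
    inside[todo] <- points_in_geom(px[todo], py[todo], geom)
  }
  inside
}

.bbox <- function(geom) {
  xs <- unlist(lapply(geom, function(r) r[, 1]))
  ys <- unlist(lapply(geom, function(r) r[, 2]))
  c(min(xs), min(ys), max(xs), max(ys))
}

# Segment intersection, inclusive of endpoints and collinear overlap:
# boundary touching counts as intersecting.
.segments_cross <- function(p1x, p1y, p2x, p2y, q1x, q1y, q2x, q2y) {
  orient <- function(ax, ay, bx, by, cx, cy)
    sign((bx - ax) * (cy - ay) - (by - ay) * (cx - ax))
  on_seg <- function(ax, ay, bx, by, cx, cy)
    cx >= pmin(ax, bx) - 1e-12 & cx <= pmax(ax, bx) + 1e-12 &
    cy >= pmin(ay, by) - 1e-12 & cy <= pmax(ay, by) + 1e-12
  o1 <- orient(p1x, p1y, p2x, p2y, q1x, q1y)
  o2 <- orient(p1x, p1y, p2x, p2y, q2x, q2y)
  o3 <- orient(q1x, q1y, q2x, q2y, p1x, p1y)
  o4 <- orient(q1x, q1y, q2x, q2y, p2x, p2y)
  res <- (o1 != o2) & (o3 != o4)
  res | (o1 == 0 & on_seg(p1x, p1y, p2x, p2y, q1x, q1y)) |
        (o2 == 0 & on_seg(p1x, p1y, p2x, p2y, q2x, q2y)) |
        (o3 == 0 & on_seg(q1x, q1y, q2x, q2y, p1x, p1y)) |
        (o4 == 0 & on_seg(q1x, q1y, q2x, q2y, p2x, p2y))
}

#' Do two geometries intersect?
#'
#' True when any boundary segments cross or touch (a single shared vertex
#' counts), or when either geometry contains a vertex of the other.
#' @param ga,gb Geometries (lists of closed rings).
#' @return Logical scalar.
#' @export
geoms_intersect <- function(ga, gb) {
  ba <- .bbox(ga); bb <- .bbox(gb)
  if (ba[1] > bb[3] || bb[1] > ba[3] || ba[2] > bb[4] || bb[2] > ba[4])
    return(FALSE)
  for (ra in ga) {
    va <- points_in_geom(ra[, 1], ra[, 2], gb)
    if (any(va)) return(TRUE)
  }
  for (rb in gb) {
    vb <- points_in_geom(rb[, 1], rb[, 2], ga)
    if (any(vb)) return(TRUE)
  }
  for (ra in ga) {
    na <- nrow(ra) - 1L
    for (rb in gb) {
      nb <- nrow(rb) - 1L
      for (i in seq_len(na)) {
        hit <- .segments_cross(ra[i, 1], ra[i, 2], ra[i + 1, 1], ra[i + 1, 2],
                               rb[-(nb + 1), 1], rb[-(nb + 1), 2],
                               rb[-1, 1], rb[-1, 2])
        if (any(hit)) return(TRUE)
      }
    }
  }
  FALSE
}

#' Which geometries of a set intersect a given geometry?
#' @param ps A [ts_polyset()].
#' @param geom A geometry.
#' @return Logical vector over `ps` geometries.
#' @export
polyset_intersecting <- function(ps, geom) {
  vapply(ps$geometries, function(g) geoms_intersect(g, geom), NA)
}

# ---- connected-component labeling ------------------------------------------

.offsets4 <- cbind(dr = c(-1L, 1L, 0L, 0L), dc = c(0L, 0L, -1L, 1L))
.offsets8 <- rbind(.offsets4,
                   cbind(dr = c(-1L, -1L, 1L, 1L), dc = c(-1L, 1L, -1L, 1L)))

.shift_mat <- function(m, dr, dc, fill = NA) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1L, 1L + dr):min(nr, nr + dr)
  cs <- max(1L, 1L + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc, drop = FALSE]
  out
}

#' Label connected components of similar-valued cells
#'
#' Two adjacent finite cells belong to the same component when their values
#' differ by less than `tol` (single-linkage over the adjacency graph). With
#' `tol = Inf` this is plain connected-component labeling of a mask. Labels
#' are contiguous from 1, numbered by first occurrence in row-major order.
#'
#' @param values Numeric matrix.
#' @param mask Logical matrix of cells to label (default: finite cells).
#' @param tol Edge tolerance on the absolute value difference (strict `<`).
#' @param connectivity 4 or 8 (default 8, matching diagonal-adjacent blocks).
#' @return Integer matrix of labels (`NA` outside the mask).
#' @export
label_components <- function(values, mask = NULL, tol = Inf,
                             connectivity = 8) {
  stopifnot(connectivity %in% c(4, 8))
  if (is.null(mask)) mask <- is.finite(values)
  nr <- nrow(values); nc <- ncol(values)
  lab <- matrix(NA_real_, nr, nc)
  lab[mask] <- seq_len(sum(mask))  # temp ids in column-major order
  offs <- if (connectivity == 8) .offsets8 else .offsets4
  edge_ok <- lapply(seq_len(nrow(offs)), function(i) {
    nv <- .shift_mat(values, offs[i, 1], offs[i, 2])
    ok <- mask & .shift_mat(mask, offs[i, 1], offs[i, 2], FALSE)
    if (is.finite(tol)) ok & abs(nv - values) < tol else ok
  })
  repeat {
    changed <- FALSE
    for (i in seq_len(nrow(offs))) {
      nb <- .shift_mat(lab, offs[i, 1], offs[i, 2])
      upd <- edge_ok[[i]] & !is.na(nb) & nb < lab
      if (any(upd, na.rm = TRUE)) {
        lab[which(upd)] <- nb[which(upd)]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  # renumber contiguously by first occurrence scanning rows left-to-right
  order_rm <- as.vector(t(lab))
  first <- unique(order_rm[!is.na(order_rm)])
  remap <- integer(max(first))
  remap[first] <- seq_along(first)
  out <- matrix(NA_integer_, nr, nc)
  out[!is.na(lab)] <- remap[lab[!is.na(lab)]]
  out
}

# ---- polygonize / rasterize -------------------------------------------------

# Trace boundary rings of the cell set `cells` (2-col matrix of row, col) on
# `grid`. Directed cell edges keep the interior on the left; at pinch vertices
# (8-connected diagonal touches) the sharpest left turn is taken so each ring
# stays simple. Returns a list of closed rings in map coordinates.
.trace_rings <- function(cells, grid) {
  nr <- grid$n_rows; nc <- grid$n_cols
  inset <- matrix(FALSE, nr + 2L, nc + 2L)       # padded membership
  inset[cbind(cells[, 1] + 1L, cells[, 2] + 1L)] <- TRUE
  r <- cells[, 1]; c <- cells[, 2]
  vid <- function(i, j) i * (nc + 1L) + j        # vertex (i, j), i,j in 0..nr/nc
  edges_start <- integer(0); edges_end <- integer(0); edges_dir <- integer(0)
  add <- function(keep, s, e, d) {
    edges_start <<- c(edges_start, s[keep])
    edges_end <<- c(edges_end, e[keep])
    edges_dir <<- c(edges_dir, rep.int(d, sum(keep)))
  }
  # dir codes: 1 = +x, 2 = +y (up, decreasing row), 3 = -x, 4 = -y
  open_below <- !inset[cbind(r + 2L, c + 1L)]
  add(open_below, vid(r, c - 1L), vid(r, c), 1L)           # bottom, left->right
  open_right <- !inset[cbind(r + 1L, c + 2L)]
  add(open_right, vid(r, c), vid(r - 1L, c), 2L)           # right, bottom->top
  open_above <- !inset[cbind(r, c + 1L)]
  add(open_above, vid(r - 1L, c), vid(r - 1L, c - 1L), 3L) # top, right->left
  open_left <- !inset[cbind(r + 1L, c)]
  add(open_left, vid(r - 1L, c - 1L), vid(r, c - 1L), 4L)  # left, top->bottom
  ne <- length(edges_start)
  ord <- order(edges_start)
  starts_sorted <- edges_start[ord]
  first_at <- match(unique(starts_sorted), starts_sorted)
  lookup_start <- unique(starts_sorted)
  used <- logical(ne)
  # left-turn preference relative to incoming direction d: d+1 (mod 4) is the
  # left turn, then straight, then right turn
  pref <- function(d) (c(d + 1L, d, d + 3L) - 1L) %% 4L + 1L
  rings <- list()
  for (e0 in seq_len(ne)) {
    if (used[e0]) next
    ring_v <- edges_start[e0]
    e <- e0
    repeat {
      used[e] <- TRUE
      v <- edges_end[e]
      ring_v <- c(ring_v, v)
      if (v == edges_start[e0]) break
      slot <- match(v, lookup_start)
      i1 <- first_at[slot]
      cand <- ord[i1:min(ne, i1 + 3L)]
      cand <- cand[starts_sorted[i1:min(ne, i1 + 3L)] == v]
      cand <- cand[!used[cand]]
      if (length(cand) == 0L) stop("boundary tracing failed (open ring)")
      if (length(cand) > 1L) {
        pr <- pref(edges_dir[e])
        cand <- cand[order(match(edges_dir[cand], pr))]
      }
      e <- cand[1]
    }
    i <- ring_v %/% (nc + 1L); j <- ring_v %% (nc + 1L)
    rings[[length(rings) + 1L]] <-
      cbind(grid$origin_x + j * grid$cell_size,
            grid$origin_y - i * grid$cell_size)
  }
  rings
}

#' Convert labeled raster components to a polygon set
#'
#' Each labeled 8-connected component becomes one geometry made of the
#' boundary of the union of its cell squares (holes included). The geometry
#' area therefore equals its cell count times the cell area exactly.
#'
#' @param labels Integer matrix of component labels (`NA` = background), as
#'   produced by [label_components()].
#' @param grid The [ts_grid()] the labels live on.
#' @param values Optional numeric matrix; adds a `mean_value` attribute per
#'   component.
#' @return A [ts_polyset()] with attributes `label`, `n_cells`, `area_ha` and
#'   optionally `mean_value`.
#' @export
polygonize_labels <- function(labels, grid, values = NULL) {
  ids <- sort(unique(labels[!is.na(labels)]))
  geoms <- vector("list", length(ids))
  ncells <- integer(length(ids))
  mval <- numeric(length(ids))
  for (k in seq_along(ids)) {
    cells <- which(labels == ids[k], arr.ind = TRUE)
    geoms[[k]] <- .trace_rings(cells, grid)
    ncells[k] <- nrow(cells)
    if (!is.null(values)) mval[k] <- mean(values[cells], na.rm = TRUE)
  }
  at <- data.frame(label = ids, n_cells = ncells)
  if (!is.null(values)) at$mean_value <- mval
  ts_polyset(geoms, at)
}

#' Rasterize a polygon set onto a grid
#'
#' A cell belongs to a polygon when its center lies inside the geometry
#' (even-odd rule), matching the cell-footprint convention used by
#' [polygonize_labels()].
#'
#' @param ps A [ts_polyset()].
#' @param grid Target [ts_grid()].
#' @param field Optional attribute column name; cells get that value
#'   (later geometries overwrite earlier ones). Default: binary 0/1.
#' @return Numeric matrix on the grid (0 outside all geometries).
#' @export
rasterize_polyset <- function(ps, grid, field = NULL) {
  out <- matrix(0, grid$n_rows, grid$n_cols)
  if (n_polygons(ps) == 0L) return(out)
  cs <- grid$cell_size
  for (k in seq_len(n_polygons(ps))) {
    geom <- ps$geometries[[k]]
    bb <- .bbox(geom)
    c1 <- max(1L, floor((bb[1] - grid$origin_x) / cs) + 1L)
    c2 <- min(grid$n_cols, ceiling((bb[3] - grid$origin_x) / cs))
    r1 <- max(1L, floor((grid$origin_y - bb[4]) / cs) + 1L)
    r2 <- min(grid$n_rows, ceiling((grid$origin_y - bb[2]) / cs))
    if (c2 < c1 || r2 < r1) next
    rows <- rep(r1:r2, times = c2 - c1 + 1L)
    cols <- rep(c1:c2, each = r2 - r1 + 1L)
    px <- grid$origin_x + (cols - 0.5) * cs
    py <- grid$origin_y - (rows - 0.5) * cs
    inside <- points_in_geom(px, py, geom)
    val <- if (is.null(field)) 1 else ps$attributes[[field]][k]
    out[cbind(rows[inside], cols[inside])] <- val
  }
  out
}

# ---- GeoJSON I/O ------------------------------------------------------------

# Split a geometry's rings into GeoJSON MultiPolygon nesting: each
# counterclockwise ring opens a polygon; clockwise rings are holes assigned to
# the smallest containing outer ring.
.geom_to_multipoly <- function(geom) {
  areas <- vapply(geom, .ring_signed_area, 0)
  outer <- which(areas > 0); holes <- which(areas <= 0)
  if (length(outer) == 0L) { outer <- seq_along(geom); holes <- integer(0) }
  polys <- lapply(outer, function(i) list(geom[[i]]))
  for (h in holes) {
    ring <- geom[[h]]
    # probe point just right of the first edge midpoint = inside the cavity
    mx <- (ring[1, 1] + ring[2, 1]) / 2; my <- (ring[1, 2] + ring[2, 2]) / 2
    dx <- ring[2, 1] - ring[1, 1]; dy <- ring[2, 2] - ring[1, 2]
    len <- sqrt(dx^2 + dy^2); eps <- len / 4
    pxy <- c(mx + dy / len * eps, my - dx / len * eps)
    cand <- outer[vapply(outer, function(i)
      isTRUE(points_in_geom(pxy[1], pxy[2], list(geom[[i]]))), NA)]
    if (length(cand) == 0L) cand <- outer
    tgt <- cand[which.min(abs(areas[cand]))]
    k <- match(tgt, outer)
    polys[[k]] <- c(polys[[k]], list(ring))
  }
  polys
}

#' Write a polygon set to GeoJSON
#'
#' Geometries become MultiPolygon features carrying the attribute table as
#' properties; the CRS id (if supplied) is recorded as a foreign `crs_id`
#' member.
#'
#' @param ps A [ts_polyset()].
#' @param path Output path (`.geojson` / `.json`).
#' @param crs_id Optional CRS identifier string stored with the file.
#' @return Invisibly, `path`.
#' @export
write_polygons <- function(ps, path, crs_id = NULL) {
  feats <- lapply(seq_len(n_polygons(ps)), function(k) {
    mp <- .geom_to_multipoly(ps$geometries[[k]])
    coords <- lapply(mp, function(poly)
      lapply(poly, function(ring) unname(lapply(seq_len(nrow(ring)),
                                                function(i) ring[i, ]))))
    props <- as.list(ps$attributes[k, , drop = FALSE])
    props <- lapply(props, function(v) if (is.factor(v)) as.character(v) else v)
    list(type = "Feature",
         geometry = list(type = "MultiPolygon", coordinates = coords),
         properties = props)
  })
  obj <- list(type = "FeatureCollection", features = feats)
  if (!is.null(crs_id)) obj$crs_id <- crs_id
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a polygon set from GeoJSON
#'
#' Accepts FeatureCollections of Polygon or MultiPolygon features; properties
#' become the attribute table. This is the polygon exchange format of the
#' package (detected by `.geojson` / `.json` extension).
#'
#' @param path File path.
#' @return A [ts_polyset()].
#' @export
read_polygons <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("geojson", "json"))
    stop("unsupported polygon format '.", ext, "' (use GeoJSON)")
  if (!file.exists(path)) stop("file not found: ", path)
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(obj$type, "FeatureCollection"))
    stop("expected a GeoJSON FeatureCollection")
  close_ring <- function(m) {
    if (any(abs(m[1, ] - m[nrow(m), ]) > 1e-9)) m <- rbind(m, m[1, ])
    m
  }
  geoms <- list(); props <- list()
  for (f in obj$features) {
    gt <- f$geometry$type
    cc <- f$geometry$coordinates
    polys <- if (identical(gt, "Polygon")) list(cc)
      else if (identical(gt, "MultiPolygon")) cc
      else stop("unsupported geometry type: ", gt)
    rings <- list()
    for (poly in polys)
      for (ring in poly)
        rings[[length(rings) + 1L]] <-
          close_ring(do.call(rbind, lapply(ring, unlist)))
    geoms[[length(geoms) + 1L]] <- rings
    props[[length(geoms)]] <- f$properties %||% list()
  }
  nm <- unique(unlist(lapply(props, names)))
  at <- do.call(rbind, lapply(props, function(p) {
    vals <- lapply(nm, function(cl) if (is.null(p[[cl]])) NA else p[[cl]])
    names(vals) <- nm
    as.data.frame(vals, optional = TRUE, stringsAsFactors = FALSE)
  }))
  if (is.null(at)) at <- data.frame(row.names = seq_along(geoms))
  rownames(at) <- NULL
  ts_polyset(geoms, at)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
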