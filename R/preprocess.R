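# Radiometric harmonization between acquisition years and band preparation.

#' Histogram-match a raster to a reference
#'
#' Per band, builds empirical CDFs on 1024 equal-width bins spanning the joint
#' source/reference range and maps each source value through the source CDF
#' and the inverse reference CDF (piecewise-linear between bin edges). This
#' removes inter-annual radiometric offsets (sun angle, atmosphere) so the
#' matched image's value distribution agrees with the reference within one bin
#' width. Used in cascade: each year is matched to the already-matched
#' previous year.
#'
#' @param source,reference [ts_raster()] objects with the same band count and
#'   grid. Bands are matched positionally.
#' @param n_bins Number of histogram bins (default 1024). Quantization error
#'   is one bin width (`range / n_bins`) wherever the distributions are
#'   dense; in sparse tails it is bounded by the local sample spacing of the
#'   reference instead.
#' @return A [ts_raster()] on the source grid with matched values; `NA`
#'   preserved. A constant-valued source band is returned unchanged with a
#'   warning (its CDF is not invertible).
#' @export
histogram_match <- function(source, reference, n_bins = 1024L) {
  assert_same_grid(source, reference)
  if (n_bands(source) != n_bands(reference))
    stop("source and reference must have the same number of bands")
  out <- source$bands
  for (i in seq_len(n_bands(source))) {
    s <- source$bands[[i]]; r <- reference$bands[[i]]
    sv <- s[is.finite(s)]; rv <- r[is.finite(r)]
    if (length(sv) == 0L || length(rv) == 0L) next
    if (max(sv) - min(sv) < .Machine$double.eps * 10) {
      warning("band ", names(source$bands)[i],
              " is constant; histogram matching skipped")
      next
    }
    lo <- min(sv, rv); hi <- max(sv, rv)
    edges <- seq(lo, hi, length.out = n_bins + 1L)
    cdf <- function(v) {
      h <- graphics::hist(v, breaks = edges, plot = FALSE)$counts
      c(0, cumsum(h)) / length(v)
    }
    cs <- cdf(sv); cr <- cdf(rv)
    fs <- stats::approx(edges, cs, xout = s[is.finite(s)], rule = 2)$y
    # exact inverse of the piecewise-linear reference CDF, infimum
    # convention: Q(p) = inf{x : F(x) >= p}, so flat empty-bin runs are
    # skipped and p = 1 maps to the end of the last mass bin
    j <- findInterval(fs, cr, left.open = TRUE) + 1L  # first cr[j] >= p
    j <- pmin(pmax(j, 1L), length(cr))
    k <- pmax(j - 1L, 1L)                             # mass bin index
    denom <- cr[k + 1L] - cr[k]
    frac <- ifelse(denom > 0, (fs - cr[k]) / denom, 0)
    frac <- pmin(pmax(frac, 0), 1)
    inv <- edges[k] + frac * (edges[k + 1L] - edges[k])
    m <- s
    m[is.finite(s)] <- inv
    out[[i]] <- m
  }
  ts_raster(source$grid, out)
}

#' Bilinearly upsample a raster to a finer grid
#'
#' Interpolates between source cell centers; exact for planar (linear) fields.
#' Target cell centers outside the hull of source centers clamp to the nearest
#' source row/column. Only upsampling is supported: the target cell size must
#' divide the source cell size.
#'
#' @param raster Source [ts_raster()] (e.g. a 20 m SWIR band).
#' @param target Target [ts_grid()] covering the same extent at finer
#'   resolution (e.g. 10 m).
#' @return A [ts_raster()] on the target grid. Any `NA` source neighbor with
#'   non-zero weight makes the target cell `NA`.
#' @export
upsample_bilinear <- function(raster, target) {
  g <- raster$grid
  if (target$cell_size >= g$cell_size)
    stop("target grid must be finer than the source (this operation only upsamples)")
  ratio <- g$cell_size / target$cell_size
  if (abs(ratio - round(ratio)) > 1e-9)
    stop("target cell size must divide the source cell size")
  ctr <- cell_centers(target)
  # fractional position in source cell-center coordinates (1..n)
  u <- (ctr$x - g$origin_x) / g$cell_size + 0.5
  v <- (g$origin_y - ctr$y) / g$cell_size + 0.5
  u <- pmin(pmax(u, 1), g$n_cols); v <- pmin(pmax(v, 1), g$n_rows)
  c0 <- pmin(floor(u), g$n_cols - 1L); c0[g$n_cols == 1L] <- 1L
  r0 <- pmin(floor(v), g$n_rows - 1L); r0[g$n_rows == 1L] <- 1L
  fu <- u - c0; fv <- v - r0
  c1 <- pmin(c0 + 1L, g$n_cols); r1 <- pmin(r0 + 1L, g$n_rows)
  out_bands <- lapply(raster$bands, function(b) {
    q11 <- b[cbind(r0, c0)]; q12 <- b[cbind(r0, c1)]
    q21 <- b[cbind(r1, c0)]; q22 <- b[cbind(r1, c1)]
    val <- (1 - fv) * ((1 - fu) * q11 + fu * q12) +
           fv * ((1 - fu) * q21 + fu * q22)
    matrix(val, target$n_rows, target$n_cols)
  })
  ts_raster(target, out_bands)
}

#' Apply a binary mask to a raster
#'
#' Cells where the mask is 0 (or nodata) become `NA` in every band; cells
#' where the mask is 1 pass through. Idempotent.
#'
#' @param raster A [ts_raster()].
#' @param mask A one-band [ts_raster()] (or matrix) with values in
#'   `{0, 1, NA}` on the same grid.
#' @return A masked [ts_raster()].
#' @export
apply_mask <- function(raster, mask) {
  m <- if (inherits(mask, "ts_raster")) {
    assert_same_grid(raster, mask)
    mask$bands[[1]]
  } else mask
  if (!all(dim(m) == c(raster$grid$n_rows, raster$grid$n_cols)))
    stop("mask dimensions do not match the raster grid")
  vals <- m[!is.na(m)]
  if (!all(vals %in% c(0, 1)))
    stop("mask must be binary (values 0/1 or nodata)")
  drop <- is.na(m) | m == 0
  ts_raster(raster$grid,
            lapply(raster$bands, function(b) { b[drop] <- NA; b }))
}
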