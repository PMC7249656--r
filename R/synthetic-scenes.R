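# Synthetic paired-year scenes with planted, georeferenced treatment truth.
#
# The generator emulates the signal structure the detection method relies on:
# spatially autocorrelated healthy-forest reflectance in five bands
# (B, G, R, NIR, SWIR; unitless surface-reflectance-like values in [0, 1]),
# planted clearcut footprints (strong post-year NIR drop with Red/SWIR rise),
# thinning footprints (the same signature at lower amplitude), prescribed-fire
# footprints (NBR drop: NIR down, SWIR up), a wildfire with its perimeter
# polygon supplied, and confusers (an agricultural green-to-plowed patch
# outside the forest mask and a shadow patch scaling all bands down).
#
# All random elements are drawn in one fixed order (base fields, clearcuts,
# thinnings, prescribed fires, wildfires, confusers) so that, for a given
# seed, adding confusers does not perturb treatment placement. The generator
# is R's default Mersenne-Twister stream seeded once with `spec$seed`.

.band_means <- c(B = 0.04, G = 0.07, R = 0.05, NIR = 0.35, SWIR = 0.16)

#' Specify a synthetic scene
#'
#' Defaults are the package's reference study conditions: a 240 x 240 cell
#' scene at 10 m (576 ha), 85% forest, ten mechanical treatments of at least
#' 2 ha (five clearcuts at effect 0.5, five thinnings at effect 0.2), two
#' prescribed fires, one wildfire, two confusers, reflectance noise SD 0.03
#' and an autocorrelation scale of 3 cells. The scene is sized so disturbed
#' footprints stay a small fraction (under about 7%) of the landscape, the
#' regime in which treatments are rare events and inter-year histogram
#' matching leaves their spectral contrast intact.
#'
#' @param seed Integer random seed; fixes the scene bit-for-bit.
#' @param n_rows,n_cols Grid dimensions in cells.
#' @param cell_size Cell size in meters.
#' @param forest_fraction Fraction of columns covered by the forest mask; the
#'   remaining right-hand strip is non-forest (agricultural) land.
#' @param n_clearcut,n_thinning,n_fire,n_wildfire,n_confuser Footprint counts.
#' @param clearcut_effect,thinning_effect Fractional post-year reflectance
#'   change of mechanical treatments, in (0, 1]; thinning must be weaker than
#'   clearcut.
#' @param fire_effect Fractional NIR reduction (and SWIR rise) of burned
#'   footprints.
#' @param noise_sd Reflectance noise standard deviation per band and year.
#' @param autocorr_sigma Gaussian filter scale (cells) of the reflectance
#'   fields.
#' @param min_footprint_ha Minimum treatment footprint area; footprint radii
#'   are drawn so every treatment is at least this large.
#' @param crs_id Projected CRS identifier for all outputs.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(seed = 1L, n_rows = 240L, n_cols = 240L,
                       cell_size = 10, forest_fraction = 0.85,
                       n_clearcut = 5L, n_thinning = 5L, n_fire = 2L,
                       n_wildfire = 1L, n_confuser = 2L,
                       clearcut_effect = 0.5, thinning_effect = 0.2,
                       fire_effect = 0.45, noise_sd = 0.03,
                       autocorr_sigma = 3, min_footprint_ha = 2,
                       crs_id = "EPSG:32610") {
  stopifnot(n_clearcut >= 0, n_thinning >= 0, n_fire >= 0, n_wildfire >= 0,
            n_confuser >= 0,
            clearcut_effect > 0, clearcut_effect <= 1,
            thinning_effect > 0, thinning_effect <= 1,
            thinning_effect < clearcut_effect,
            fire_effect > 0, fire_effect <= 1,
            noise_sd >= 0, forest_fraction > 0, forest_fraction <= 1,
            min_footprint_ha > 0)
  structure(list(seed = as.integer(seed), n_rows = as.integer(n_rows),
                 n_cols = as.integer(n_cols), cell_size = cell_size,
                 forest_fraction = forest_fraction,
                 n_clearcut = as.integer(n_clearcut),
                 n_thinning = as.integer(n_thinning),
                 n_fire = as.integer(n_fire),
                 n_wildfire = as.integer(n_wildfire),
                 n_confuser = as.integer(n_confuser),
                 clearcut_effect = clearcut_effect,
                 thinning_effect = thinning_effect,
                 fire_effect = fire_effect, noise_sd = noise_sd,
                 autocorr_sigma = autocorr_sigma,
                 min_footprint_ha = min_footprint_ha, crs_id = crs_id),
            class = "scene_spec")
}

# Separable Gaussian smoothing, kernel truncated at 3 sigma, edges renormalized.
.gaussian_smooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-half:half, sd = sigma)
  smooth1 <- function(x) {
    n <- length(x)
    out <- numeric(n)
    w <- numeric(n)
    for (i in seq_along(k)) {
      d <- i - half - 1L
      src <- seq_len(n) - d
      ok <- src >= 1L & src <= n
      out[ok] <- out[ok] + k[i] * x[src[ok]]
      w[ok] <- w[ok] + k[i]
    }
    out / w
  }
  m <- apply(m, 2, smooth1)
  t(apply(t(m), 2, smooth1))
}

# Autocorrelated unit-variance field.
.autocorr_field <- function(n_rows, n_cols, sigma) {
  z <- matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols)
  s <- .gaussian_smooth(z, sigma)
  (s - mean(s)) / stats::sd(s)
}

# Rasterize an ellipse footprint; returns cell index matrix (row, col).
.ellipse_cells <- function(cr, cc, a, b, theta, n_rows, n_cols) {
  rr <- max(1L, floor(cr - max(a, b))):min(n_rows, ceiling(cr + max(a, b)))
  cc2 <- max(1L, floor(cc - max(a, b))):min(n_cols, ceiling(cc + max(a, b)))
  rows <- rep(rr, times = length(cc2))
  cols <- rep(cc2, each = length(rr))
  dx <- cols - cc; dy <- rows - cr
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  cbind(row = rows[inside], col = cols[inside])
}

# Place `n` elliptical footprints avoiding `occupied` (with a 2-cell buffer)
# and restricted to columns [col_lo, col_hi]. Draws consume the RNG stream in
# a fixed order. Returns list of cell matrices; errors when a footprint cannot
# be placed within `max_try` rejections.
.place_footprints <- function(n, occupied, n_rows, n_cols, col_lo, col_hi,
                              r_lo, r_hi, max_try = 500L) {
  out <- vector("list", n)
  grown <- occupied
  for (k in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(max_try)) {
      a <- stats::runif(1, r_lo, r_hi); b <- stats::runif(1, r_lo, r_hi)
      theta <- stats::runif(1, 0, pi)
      margin <- ceiling(max(a, b)) + 1L
      if (col_hi - margin < col_lo + margin || n_rows - margin < 1L + margin)
        stop("scene too small for the requested footprint radii")
      cr <- stats::runif(1, 1 + margin, n_rows - margin)
      cc <- stats::runif(1, col_lo + margin, col_hi - margin)
      cells <- .ellipse_cells(cr, cc, a, b, theta, n_rows, n_cols)
      buf <- .ellipse_cells(cr, cc, a + 2, b + 2, theta, n_rows, n_cols)
      if (nrow(cells) > 0L && !any(grown[buf])) {
        out[[k]] <- cells
        grown[cells] <- TRUE
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("could not place footprint ", k, " without overlap after ",
           max_try, " retries; reduce counts or enlarge the scene")
  }
  out
}

#' Generate a synthetic scene with treatment truth
#'
#' Deterministic for a fixed `spec$seed`. Produces pre- and post-year
#' five-band rasters, the forest mask, treatment truth polygons (typed
#' `clearcut`, `thinning`, `prescribed_fire`), wildfire perimeter polygons,
#' and per-date binary burned-area rasters (prescribed fires split across two
#' dates; the wildfire burn is included so perimeter filtering has work to
#' do).
#'
#' @param spec A [scene_spec()].
#' @return An object of class `scene_truth` with fields `pre`, `post`
#'   ([ts_raster()], bands `B`, `G`, `R`, `NIR`, `SWIR`), `forest_mask`
#'   (one-band 0/1 [ts_raster()]), `treatments`, `wildfire_perimeters`
#'   ([ts_polyset()]), `burned_area_rasters` (list of binary [ts_raster()])
#'   and `spec`.
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  set.seed(spec$seed)
  nr <- spec$n_rows; nc <- spec$n_cols
  grid <- ts_grid(500000, 5200000, spec$cell_size, nr, nc,
                  crs_id = spec$crs_id)

  # 1. base reflectance fields, fixed draw order: persistent brightness field
  # first, then per-band/per-year noise (pre year, then post year).
  # Canopy-density and illumination variation act multiplicatively on all
  # bands at once (coefficient of variation 0.1), giving the rank-one
  # dominant inter-band covariance of real vegetation imagery on which
  # stable principal components rest; per-band autocorrelated noise of SD
  # `noise_sd` is added independently per year.
  # Noise is proportional to band reflectance (sensor and atmospheric
  # residuals scale with signal); `noise_sd` is the absolute SD of the
  # brightest band (NIR), so darker bands are proportionally quieter.
  brightness <- .autocorr_field(nr, nc, spec$autocorr_sigma)
  nir_mean <- .band_means[["NIR"]]
  mk_year <- function() {
    bands <- lapply(.band_means, function(mu)
      mu * (1 + 0.1 * brightness) +
        spec$noise_sd * (mu / nir_mean) *
          .autocorr_field(nr, nc, spec$autocorr_sigma))
    names(bands) <- names(.band_means)
    bands
  }
  pre_b <- mk_year(); post_b <- mk_year()

  # deterministic forest mask: right-hand strip is non-forest
  forest_cols <- round(nc * spec$forest_fraction)
  if (forest_cols < 1L) stop("forest_fraction leaves no forest columns")
  fmask <- matrix(0, nr, nc); fmask[, seq_len(forest_cols)] <- 1

  # footprint radii from the minimum area: pi * r_lo^2 cells >= min area
  cell_ha <- cell_area_ha(grid)
  r_lo <- sqrt(spec$min_footprint_ha / cell_ha / pi) + 0.8
  r_hi <- r_lo * 1.3
  occupied <- matrix(FALSE, nr, nc)

  # 2-5. footprints in fixed order: clearcut, thinning, fire, wildfire
  place <- function(n, lo = 1L, hi = forest_cols, scale = 1) {
    fp <- .place_footprints(n, occupied, nr, nc, lo, hi,
                            r_lo * scale, r_hi * scale)
    for (cells in fp) occupied[cells] <<- TRUE
    fp
  }
  fp_cc <- place(spec$n_clearcut)
  fp_th <- place(spec$n_thinning)
  fp_fi <- place(spec$n_fire)
  fp_wf <- place(spec$n_wildfire, scale = 1.4)

  # 6. confusers: agricultural patches outside the forest, shadow inside
  n_ag <- ceiling(spec$n_confuser / 2); n_sh <- spec$n_confuser - n_ag
  fp_ag <- if (n_ag > 0 && forest_cols < nc)
    place(n_ag, lo = forest_cols + 1L, hi = nc, scale = 0.45) else list()
  fp_sh <- if (n_sh > 0) place(n_sh, scale = 0.7) else list()

  scale_cells <- function(bands, cells, factors) {
    for (bn in names(factors))
      bands[[bn]][cells] <- bands[[bn]][cells] * factors[[bn]]
    bands
  }
  e_cc <- spec$clearcut_effect; e_th <- spec$thinning_effect
  e_fi <- spec$fire_effect
  for (cells in fp_cc)
    post_b <- scale_cells(post_b, cells,
                          list(NIR = 1 - e_cc, R = 1 + e_cc, SWIR = 1 + e_cc,
                               G = 1 + 0.5 * e_cc))
  for (cells in fp_th)
    post_b <- scale_cells(post_b, cells,
                          list(NIR = 1 - e_th, R = 1 + e_th, SWIR = 1 + e_th,
                               G = 1 + 0.5 * e_th))
  for (cells in c(fp_fi, fp_wf))
    post_b <- scale_cells(post_b, cells,
                          list(NIR = 1 - e_fi, SWIR = 1 + e_fi,
                               R = 1 + 0.3 * e_fi))
  for (cells in fp_ag) {
    # green cropland in the pre year, plowed after: NIR collapses, Red rises
    pre_b <- scale_cells(pre_b, cells, list(NIR = 1.3))
    post_b <- scale_cells(post_b, cells,
                          list(NIR = 0.35, R = 1.8, SWIR = 1.3))
  }
  for (cells in fp_sh)
    post_b <- scale_cells(post_b, cells,
                          list(B = 0.4, G = 0.4, R = 0.4, NIR = 0.4,
                               SWIR = 0.4))

  clamp01 <- function(m) pmin(pmax(m, 0), 1)
  pre_b <- lapply(pre_b, clamp01); post_b <- lapply(post_b, clamp01)

  fp_polyset <- function(fps, type) {
    if (length(fps) == 0L)
      return(ts_polyset(list(), data.frame(type = character(0))))
    geoms <- lapply(fps, function(cells) {
      m <- matrix(NA_real_, nr, nc); m[cells] <- 1
      lab <- label_components(m)
      ps <- polygonize_labels(lab, grid)
      if (n_polygons(ps) != 1L)  # ellipses rasterize to one component
        stop("footprint polygonized to ", n_polygons(ps), " components")
      ps$geometries[[1]]
    })
    ts_polyset(geoms, data.frame(type = rep(type, length(fps)),
                                 stringsAsFactors = FALSE))
  }
  treatments <- bind_polysets(
    bind_polysets(fp_polyset(fp_cc, "clearcut"),
                  fp_polyset(fp_th, "thinning")),
    fp_polyset(fp_fi, "prescribed_fire"))
  perimeters <- fp_polyset(fp_wf, "wildfire")

  burn_date <- function(fps) {
    m <- matrix(0, nr, nc)
    for (cells in fps) m[cells] <- 1
    ts_raster(grid, list(burned = m))
  }
  odd <- seq_along(fp_fi) %% 2L == 1L
  burned <- list(burn_date(c(fp_fi[odd], fp_wf)),
                 burn_date(fp_fi[!odd]))

  structure(list(pre = ts_raster(grid, pre_b),
                 post = ts_raster(grid, post_b),
                 forest_mask = ts_raster(grid, list(forest = fmask)),
                 treatments = treatments,
                 wildfire_perimeters = perimeters,
                 burned_area_rasters = burned,
                 spec = spec),
            class = "scene_truth")
}

#' @export
print.scene_truth <- function(x, ...) {
  tt <- table(x$treatments$attributes$type)
  cat(sprintf("<scene_truth> %d x %d cells @ %g m; treatments: %s; %d wildfire perimeter(s)\n",
              x$pre$grid$n_rows, x$pre$grid$n_cols, x$pre$grid$cell_size,
              paste(names(tt), tt, sep = "=", collapse = ", "),
              n_polygons(x$wildfire_perimeters)))
  invisible(x)
}

#' Mechanical-treatment truth polygons for training
#'
#' Returns only clearcut and thinning polygons: training targets the
#' mechanical treatments, since burned units are identified separately from
#' burned-area products.
#'
#' @param truth A [generate_scene()] result.
#' @return A [ts_polyset()] (possibly empty).
#' @export
scene_to_training_truth <- function(truth) {
  keep <- truth$treatments$attributes$type %in% c("clearcut", "thinning")
  subset_polyset(truth$treatments, keep)
}

#' Write a scene to a directory
#'
#' Writes `pre.tif`, `post.tif`, `forest_mask.tif`, `truth.geojson`,
#' `perimeters.geojson` and `burned_<i>.tif`.
#'
#' @param truth A [generate_scene()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory path.
#' @export
write_scene <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_raster(truth$pre, file.path(dir, "pre.tif"))
  write_raster(truth$post, file.path(dir, "post.tif"))
  write_raster(truth$forest_mask, file.path(dir, "forest_mask.tif"))
  write_polygons(truth$treatments, file.path(dir, "truth.geojson"),
                 crs_id = truth$pre$grid$crs_id)
  write_polygons(truth$wildfire_perimeters,
                 file.path(dir, "perimeters.geojson"),
                 crs_id = truth$pre$grid$crs_id)
  for (i in seq_along(truth$burned_area_rasters))
    write_raster(truth$burned_area_rasters[[i]],
                 file.path(dir, sprintf("burned_%d.tif", i)))
  invisible(dir)
}
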