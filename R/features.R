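# The 18-band predictor stack: per-image PCA, temporal change metrics, 3x3
# focal statistics, burn/vegetation indices, compositing and correlation
# pruning.

#' Bundle a pre/post image pair
#'
#' @param pre,post [ts_raster()] objects on an identical grid: the
#'   pre-treatment and post-treatment year images.
#' @param period_label Text label for the period (e.g. `"2016-2017"`).
#' @return An object of class `ts_scene_pair`.
#' @export
scene_pair <- function(pre, post, period_label = "pre-post") {
  assert_same_grid(pre, post)
  structure(list(pre = pre, post = post, period_label = period_label),
            class = "ts_scene_pair")
}

#' Fit a principal component transform to an image
#'
#' Components of the inter-band covariance obtained by singular value
#' decomposition of the centered pixel-by-band matrix. All components are
#' retained. The sign of each loading column is fixed so that its
#' largest-magnitude entry is positive, which prevents arbitrary SVD sign
#' flips from corrupting downstream change metrics.
#'
#' @param image A [ts_raster()] with at least 2 bands.
#' @param mask Optional logical matrix or binary [ts_raster()]: only cells
#'   where the mask is 1/`TRUE` enter the fit (e.g. forest cells).
#' @return An object of class `ts_pca` with fields `band_means`, `loadings`
#'   (orthonormal, bands x components), `explained_variance` and `band_names`.
#' @export
fit_pca <- function(image, mask = NULL) {
  nb <- n_bands(image)
  if (nb < 2L) stop("PCA needs at least 2 bands")
  X <- sapply(image$bands, as.vector)
  keep <- rowSums(is.na(X)) == 0L
  if (!is.null(mask)) {
    m <- if (inherits(mask, "ts_raster")) mask$bands[[1]] else mask
    keep <- keep & !is.na(as.vector(m)) & as.vector(m) == 1
  }
  X <- X[keep, , drop = FALSE]
  if (nrow(X) < nb + 1L) stop("PCA needs at least bands + 1 finite pixels")
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  L <- pc$rotation
  for (j in seq_len(ncol(L)))
    if (L[which.max(abs(L[, j])), j] < 0) L[, j] <- -L[, j]
  structure(list(band_means = pc$center, loadings = L,
                 explained_variance = pc$sdev^2,
                 band_names = names(image$bands)),
            class = "ts_pca")
}

#' Project an image onto fitted principal components
#'
#' Per-pixel centered projection onto the loadings; one output band per
#' component (`PC1`, `PC2`, ...). Any `NA` band value makes all scores of
#' that pixel `NA`.
#'
#' @param image A [ts_raster()] whose band count matches the model.
#' @param model A [fit_pca()] model.
#' @return A [ts_raster()] of component scores.
#' @export
pca_scores <- function(image, model) {
  nb <- n_bands(image)
  if (nb != nrow(model$loadings))
    stop("band count does not match the PCA model")
  X <- vapply(image$bands, as.vector,
              numeric(image$grid$n_rows * image$grid$n_cols))
  X <- matrix(X, ncol = nb)
  ok <- rowSums(is.na(X)) == 0L
  S <- matrix(NA_real_, nrow(X), ncol(model$loadings))
  if (any(ok))
    S[ok, ] <- sweep(X[ok, , drop = FALSE], 2, model$band_means) %*%
      model$loadings
  g <- image$grid
  bands <- lapply(seq_len(ncol(S)), function(j)
    matrix(S[, j], g$n_rows, g$n_cols))
  names(bands) <- paste0("PC", seq_along(bands))
  ts_raster(g, bands)
}

#' Principal-component temporal change metrics
#'
#' Fits a PCA to each year's image independently and combines the component
#' scores per band index `i`: `subtract` gives `PC_i(post) - PC_i(pre)`;
#' `divide` gives `PC_i(pre) / PC_i(post)` (note the opposite orientation of
#' the two metrics, kept exactly as defined). Component correspondence across
#' years is by index.
#'
#' @param pair A [scene_pair()]; the images entering the PCA (commonly the
#'   four 10 m bands).
#' @param mode `"subtract"` or `"divide"`.
#' @param mask Optional fit mask passed to [fit_pca()] for both years.
#' @param eps Division guard: cells with `|denominator| < eps` become `NA` in
#'   divide mode.
#' @return A [ts_raster()] with one change band per component.
#' @export
pca_change <- function(pair, mode = c("subtract", "divide"), mask = NULL,
                       eps = 1e-9) {
  mode <- match.arg(mode)
  s_pre <- pca_scores(pair$pre, fit_pca(pair$pre, mask))
  s_post <- pca_scores(pair$post, fit_pca(pair$post, mask))
  pca_change_scores(s_pre, s_post, mode, eps)
}

#' Combine precomputed component scores into a change raster
#'
#' @param scores_pre,scores_post [ts_raster()] score rasters for the pre and
#'   post year, one band per component.
#' @param mode `"subtract"` (post minus pre) or `"divide"` (pre over post).
#' @param eps Division guard for `divide` mode.
#' @return A [ts_raster()] of change metrics.
#' @export
pca_change_scores <- function(scores_pre, scores_post,
                              mode = c("subtract", "divide"), eps = 1e-9) {
  mode <- match.arg(mode)
  assert_same_grid(scores_pre, scores_post)
  if (n_bands(scores_pre) != n_bands(scores_post))
    stop("score rasters must have the same number of components")
  bands <- lapply(seq_len(n_bands(scores_pre)), function(i) {
    pre <- scores_pre$bands[[i]]; post <- scores_post$bands[[i]]
    if (mode == "subtract") post - pre
    else {
      out <- pre / post
      out[abs(post) < eps] <- NA
      out
    }
  })
  names(bands) <- paste0(if (mode == "subtract") "sub_PC" else "div_PC",
                         seq_along(bands))
  ts_raster(scores_pre$grid, bands)
}

#' Focal (moving window) statistics
#'
#' Per band and per cell, the mean or population standard deviation over the
#' 3x3 neighborhood of finite cells. Edge cells use the neighbors that exist
#' (>= 4 of them); `NA` cells are excluded from the statistic, and a cell with
#' no finite neighbor stays `NA`.
#'
#' @param raster A [ts_raster()].
#' @param stat `"mean"` or `"std"` (population denominator, the GIS focal
#'   convention).
#' @return A [ts_raster()] of the same shape.
#' @export
focal_stats <- function(raster, stat = c("mean", "std")) {
  stat <- match.arg(stat)
  offs <- expand.grid(dr = -1:1, dc = -1:1)
  bands <- lapply(raster$bands, function(b) {
    s <- matrix(0, nrow(b), ncol(b)); s2 <- s; n <- s
    for (i in seq_len(nrow(offs))) {
      nb <- .shift_mat(b, offs$dr[i], offs$dc[i])
      ok <- !is.na(nb)
      nbz <- nb; nbz[!ok] <- 0
      s <- s + nbz; s2 <- s2 + nbz^2; n <- n + ok
    }
    mu <- s / n
    mu[n == 0] <- NA
    if (stat == "mean") mu
    else sqrt(pmax(s2 / n - mu^2, 0))
  })
  ts_raster(raster$grid, bands)
}

#' Burn and vegetation spectral indices for an image pair
#'
#' Computes, from the NIR, Red and (already upsampled) SWIR bands:
#' \itemize{
#'   \item `NBR_pre`, `NBR_post`: normalized burn ratio
#'     `(NIR - SWIR) / (NIR + SWIR)` per year;
#'   \item `dNBR = NBR_pre - NBR_post`;
#'   \item `RBR = dNBR / (NBR_pre + 1.001)`, the relativized burn ratio,
#'     which remains informative where pre-fire vegetation cover is low;
#'   \item `NDVI = (NIR - Red) / (NIR + Red)` on the post-year image.
#' }
#' Zero denominators give `NA`.
#'
#' @param pair A [scene_pair()] whose images carry bands named `NIR`, `R`
#'   (red) and `SWIR`.
#' @param ndvi_year `"post"` (default) or `"pre"`: which image NDVI uses.
#' @return A [ts_raster()] with bands `NBR_pre`, `NBR_post`, `dNBR`, `RBR`,
#'   `NDVI`.
#' @export
spectral_indices <- function(pair, ndvi_year = c("post", "pre")) {
  ndvi_year <- match.arg(ndvi_year)
  need <- c("NIR", "R", "SWIR")
  for (img in list(pair$pre, pair$post))
    if (!all(need %in% names(img$bands)))
      stop("pair images must carry bands NIR, R and SWIR")
  safe_ratio <- function(num, den) {
    out <- num / den
    out[den == 0] <- NA
    out
  }
  nbr <- function(img)
    safe_ratio(band(img, "NIR") - band(img, "SWIR"),
               band(img, "NIR") + band(img, "SWIR"))
  nbr_pre <- nbr(pair$pre); nbr_post <- nbr(pair$post)
  dnbr <- nbr_pre - nbr_post
  rbr <- safe_ratio(dnbr, nbr_pre + 1.001)
  nimg <- if (ndvi_year == "post") pair$post else pair$pre
  ndvi <- safe_ratio(band(nimg, "NIR") - band(nimg, "R"),
                     band(nimg, "NIR") + band(nimg, "R"))
  ts_raster(pair$pre$grid,
            list(NBR_pre = nbr_pre, NBR_post = nbr_post, dNBR = dnbr,
                 RBR = rbr, NDVI = ndvi))
}

#' Build the 18-band predictor stack for a scene pair
#'
#' Fits a PCA per year on the four 10 m bands (`B`, `G`, `R`, `NIR`), forms
#' the subtraction and division change metrics, applies 3x3 focal mean and
#' standard deviation to each, and appends RBR and NDVI. Stack order (= band
#' rank, 1 is highest priority): bands 1-4 focal mean of the subtraction
#' metric (PC1..PC4), 5-8 focal STD of subtraction, 9-12 focal mean of
#' division, 13-16 focal STD of division, 17 RBR, 18 NDVI.
#'
#' @param pair A [scene_pair()] with bands `B`, `G`, `R`, `NIR` and,
#'   for RBR, `SWIR`. Without SWIR the RBR band is omitted with a warning
#'   (17-band stack, flagged non-standard).
#' @param mask Optional PCA fit mask (e.g. forest cells), passed to
#'   [fit_pca()].
#' @return An object of class `ts_predictor_stack`: a list with `raster`
#'   (the stacked [ts_raster()]), `band_meta` (per-band source, component and
#'   rank) and `kept` (logical flags, all `TRUE` before pruning).
#' @export
compose_predictors <- function(pair, mask = NULL) {
  four <- c("B", "G", "R", "NIR")
  if (!all(four %in% names(pair$pre$bands)))
    stop("pair images must carry bands B, G, R, NIR")
  pre4 <- subset_bands(pair$pre, four); post4 <- subset_bands(pair$post, four)
  s_pre <- pca_scores(pre4, fit_pca(pre4, mask))
  s_post <- pca_scores(post4, fit_pca(post4, mask))
  sub <- pca_change_scores(s_pre, s_post, "subtract")
  div <- pca_change_scores(s_pre, s_post, "divide")
  fm_sub <- focal_stats(sub, "mean"); fs_sub <- focal_stats(sub, "std")
  fm_div <- focal_stats(div, "mean"); fs_div <- focal_stats(div, "std")
  has_swir <- "SWIR" %in% names(pair$pre$bands) &&
    "SWIR" %in% names(pair$post$bands)
  bands <- c(stats::setNames(fm_sub$bands, paste0("fmean_sub_PC", 1:4)),
             stats::setNames(fs_sub$bands, paste0("fstd_sub_PC", 1:4)),
             stats::setNames(fm_div$bands, paste0("fmean_div_PC", 1:4)),
             stats::setNames(fs_div$bands, paste0("fstd_div_PC", 1:4)))
  meta <- data.frame(
    name = names(bands),
    source = rep(c("focal_mean_PCAsub", "focal_std_PCAsub",
                   "focal_mean_PCAdiv", "focal_std_PCAdiv"), each = 4),
    component = rep(1:4, times = 4),
    stringsAsFactors = FALSE)
  if (has_swir) {
    idx <- spectral_indices(pair)
    bands$RBR <- band(idx, "RBR")
    bands$NDVI <- band(idx, "NDVI")
    meta <- rbind(meta, data.frame(name = c("RBR", "NDVI"),
                                   source = c("RBR", "NDVI"),
                                   component = NA_integer_))
  } else {
    warning("no SWIR band: RBR omitted; stack has 17 bands (non-standard)")
    ndvi <- {
      num <- band(pair$post, "NIR") - band(pair$post, "R")
      den <- band(pair$post, "NIR") + band(pair$post, "R")
      out <- num / den; out[den == 0] <- NA; out
    }
    bands$NDVI <- ndvi
    meta <- rbind(meta, data.frame(name = "NDVI", source = "NDVI",
                                   component = NA_integer_))
  }
  meta$rank <- seq_len(nrow(meta))
  structure(list(raster = ts_raster(pair$pre$grid, bands),
                 band_meta = meta,
                 kept = stats::setNames(rep(TRUE, nrow(meta)), meta$name),
                 standard = has_swir),
            class = "ts_predictor_stack")
}

#' @export
print.ts_predictor_stack <- function(x, ...) {
  cat(sprintf("<ts_predictor_stack> %d bands (%d kept) on %d x %d grid\n",
              nrow(x$band_meta), sum(x$kept),
              x$raster$grid$n_rows, x$raster$grid$n_cols))
  invisible(x)
}

#' Kept bands of a predictor stack
#' @param stack A [compose_predictors()] stack.
#' @return Character vector of band names with `kept = TRUE`, in rank order.
#' @export
kept_bands <- function(stack) stack$band_meta$name[stack$kept]

#' Flag redundant predictor bands by pairwise correlation
#'
#' Pearson correlations are computed over all mutually finite pixels. Band
#' pairs are visited in rank order (band 1 is the highest priority); whenever
#' a pair of still-kept bands correlates beyond the threshold in absolute
#' value, the lower-priority band (larger rank) is flagged not-kept. So if
#' band 1 correlates with band 10, band 10 is dropped. A constant band has an
#' undefined correlation and is treated as uncorrelated, with a warning.
#'
#' @param stack A [compose_predictors()] stack with at least 2 kept bands.
#' @param threshold Absolute correlation above which (strict `>`) a pair is
#'   redundant. Default 0.75.
#' @return The stack with its `kept` flags updated.
#' @export
prune_correlated <- function(stack, threshold = 0.75) {
  if (sum(stack$kept) < 2L) stop("need at least 2 kept bands")
  X <- sapply(stack$raster$bands, as.vector)
  X <- X[rowSums(is.na(X)) == 0L, , drop = FALSE]
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    warning("constant band(s) ", paste(colnames(X)[sds == 0], collapse = ", "),
            ": correlation undefined, treated as uncorrelated")
  suppressWarnings(r <- stats::cor(X))
  r[!is.finite(r)] <- 0
  kept <- stack$kept
  nb <- length(kept)
  for (i in seq_len(nb - 1L)) {
    if (!kept[i]) next
    for (j in (i + 1L):nb) {
      if (!kept[j]) next
      if (abs(r[i, j]) > threshold) kept[j] <- FALSE
    }
  }
  stack$kept <- kept
  stack
}
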