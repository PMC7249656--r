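# Brute-force focal oracle: double loop over cells and neighbors.
focal_oracle <- function(m, stat) {
  out <- matrix(NA_real_, nrow(m), ncol(m))
  for (r in seq_len(nrow(m))) {
    for (c in seq_len(ncol(m))) {
      vals <- c()
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; cc <- c + dc
        if (rr >= 1 && rr <= nrow(m) && cc >= 1 && cc <= ncol(m) &&
            !is.na(m[rr, cc]))
          vals <- c(vals, m[rr, cc])
      }
      if (length(vals))
        out[r, c] <- if (stat == "mean") mean(vals) else
          sqrt(mean(vals^2) - mean(vals)^2)
    }
  }
  out
}

test_that("PCA loadings are orthonormal and variances are conserved", {
  img <- rand_raster(12, 12, 4, seed = 31)
  p <- fit_pca(img)
  expect_equal(crossprod(p$loadings), diag(4), tolerance = 1e-10,
               ignore_attr = TRUE)
  total_var <- sum(apply(sapply(img$bands, as.vector), 2, var))
  expect_equal(sum(p$explained_variance), total_var, tolerance = 1e-8)
  # sign convention: largest-|loading| entry of each column is positive
  for (j in 1:4)
    expect_gt(p$loadings[which.max(abs(p$loadings[, j])), j], 0)
})

test_that("PCA explained variances match an eigendecomposition oracle", {
  set.seed(17)
  g <- tiny_grid(10, 5)
  X <- matrix(rnorm(50 * 4), 50, 4) %*% matrix(runif(16, -1, 1), 4, 4)
  bands <- lapply(1:4, function(j) matrix(X[, j], 10, 5))
  names(bands) <- paste0("b", 1:4)
  p <- fit_pca(ts_raster(g, bands))
  ev <- eigen(cov(X), symmetric = TRUE)$values
  expect_equal(p$explained_variance, ev, tolerance = 1e-8)
})

test_that("perfectly correlated bands give a zero second variance", {
  set.seed(5)
  b1 <- matrix(rnorm(64), 8, 8)
  p <- fit_pca(mk_raster(b1 = b1, b2 = 2 * b1))
  expect_equal(p$explained_variance[2], 0, tolerance = 1e-10)
})

test_that("scores center, reproduce variances, and invert to the input", {
  img <- rand_raster(9, 9, 4, seed = 23)
  p <- fit_pca(img)
  s <- pca_scores(img, p)
  # the band-means pixel projects to the origin
  mean_img <- ts_raster(tiny_grid(1, 1),
                        lapply(as.list(p$band_means), function(v)
                          matrix(v, 1, 1)))
  s0 <- pca_scores(mean_img, p)
  expect_equal(unname(sapply(s0$bands, as.vector)), rep(0, 4),
               tolerance = 1e-12)
  expect_equal(var(as.vector(s$bands$PC1)), p$explained_variance[1],
               tolerance = 1e-10)
  # reconstruction: scores %*% t(loadings) + means
  S <- sapply(s$bands, as.vector)
  X <- S %*% t(p$loadings) + rep(p$band_means, each = nrow(S))
  expect_equal(unname(X), unname(sapply(img$bands, as.vector)),
               tolerance = 1e-8)
  # nodata propagates to every component
  img$bands$b2[3, 3] <- NA
  s2 <- pca_scores(img, p)
  expect_true(all(is.na(sapply(s2$bands, function(b) b[3, 3]))))
})

test_that("change metrics obey their identity and worked cases", {
  g <- tiny_grid(4, 4)
  s <- ts_raster(g, list(PC1 = matrix(2, 4, 4)))
  same_sub <- pca_change_scores(s, s, "subtract")
  same_div <- pca_change_scores(s, s, "divide")
  expect_equal(same_sub$bands[[1]], matrix(0, 4, 4))
  expect_equal(same_div$bands[[1]], matrix(1, 4, 4))
  post <- ts_raster(g, list(PC1 = matrix(4, 4, 4)))
  expect_equal(pca_change_scores(s, post, "subtract")$bands[[1]][1, 1], 2)
  expect_equal(pca_change_scores(s, post, "divide")$bands[[1]][1, 1], 0.5)
  # division guard
  zero <- ts_raster(g, list(PC1 = matrix(0, 4, 4)))
  expect_true(all(is.na(pca_change_scores(s, zero, "divide")$bands[[1]])))
})

test_that("focal statistics agree with the brute-force oracle everywhere", {
  cases <- list(
    matrix(rnorm(100), 10, 10),
    matrix(rnorm(400), 20, 20),
    {
      m <- matrix(runif(150), 10, 15)
      m[sample(150, 20)] <- NA
      m
    })
  set.seed(41)
  for (m in cases) {
    r <- mk_raster(v = m)
    for (stat in c("mean", "std")) {
      got <- focal_stats(r, stat)$bands$v
      want <- focal_oracle(m, stat)
      expect_equal(got, want, tolerance = 1e-12)
    }
  }
})

test_that("focal mean of a single spike spreads 1/9 over its neighborhood", {
  m <- matrix(0, 9, 9); m[5, 5] <- 1
  fm <- focal_stats(mk_raster(v = m), "mean")$bands$v
  expect_equal(fm[4:6, 4:6], matrix(1 / 9, 3, 3))
  expect_equal(fm[1, 1], 0)
  # constant raster: mean is the constant, std is zero
  cst <- focal_stats(mk_raster(v = matrix(7, 6, 6)), "std")$bands$v
  expect_equal(cst, matrix(0, 6, 6))
})

test_that("spectral indices satisfy their identities and worked example", {
  g <- tiny_grid(2, 2)
  mk <- function(nir, r, swir)
    ts_raster(g, list(NIR = matrix(nir, 2, 2), R = matrix(r, 2, 2),
                      SWIR = matrix(swir, 2, 2)))
  # no change: dNBR and RBR are exactly zero
  pair <- scene_pair(mk(0.4, 0.05, 0.2), mk(0.4, 0.05, 0.2))
  idx <- spectral_indices(pair)
  expect_equal(band(idx, "dNBR"), matrix(0, 2, 2), tolerance = 1e-12)
  expect_equal(band(idx, "RBR"), matrix(0, 2, 2), tolerance = 1e-12)
  # NIR == Red gives NDVI exactly zero
  sym <- scene_pair(mk(0.4, 0.3, 0.2), mk(0.3, 0.3, 0.2))
  expect_equal(band(spectral_indices(sym), "NDVI"), matrix(0, 2, 2),
               tolerance = 1e-12)
  # NBR_pre 0.5, NBR_post 0.1: dNBR 0.4, RBR 0.4/1.501
  pre <- mk(0.3, 0.05, 0.1)     # NBR = 0.2/0.4 = 0.5
  post <- mk(0.275, 0.05, 0.225)  # NBR = 0.05/0.5 = 0.1
  idx2 <- spectral_indices(scene_pair(pre, post))
  expect_equal(band(idx2, "NBR_pre")[1, 1], 0.5, tolerance = 1e-12)
  expect_equal(band(idx2, "dNBR")[1, 1], 0.4, tolerance = 1e-12)
  expect_equal(band(idx2, "RBR")[1, 1], 0.4 / 1.501, tolerance = 1e-12)
  # zero denominator yields nodata
  degen <- scene_pair(mk(0, 0.05, 0), mk(0.3, 0.05, 0.1))
  expect_true(all(is.na(band(spectral_indices(degen), "NBR_pre"))))
})

test_that("NDVI stays within [-1, 1] for nonnegative reflectances", {
  set.seed(6)
  g <- tiny_grid(15, 15)
  mk <- function() matrix(runif(225, 0, 1), 15, 15)
  pair <- scene_pair(
    ts_raster(g, list(NIR = mk(), R = mk(), SWIR = mk())),
    ts_raster(g, list(NIR = mk(), R = mk(), SWIR = mk())))
  ndvi <- band(spectral_indices(pair), "NDVI")
  expect_true(all(ndvi[!is.na(ndvi)] >= -1 & ndvi[!is.na(ndvi)] <= 1))
})

test_that("the predictor stack has the contracted 18-band layout", {
  sc <- small_scene()
  pair <- scene_pair(sc$pre, sc$post)
  st <- compose_predictors(pair)
  expect_equal(nrow(st$band_meta), 18L)
  expect_equal(st$band_meta$rank, 1:18)
  expect_equal(st$band_meta$source[c(1, 5, 9, 13, 17, 18)],
               c("focal_mean_PCAsub", "focal_std_PCAsub",
                 "focal_mean_PCAdiv", "focal_std_PCAdiv", "RBR", "NDVI"))
  # band 17 equals the RBR plane bit for bit
  idx <- spectral_indices(pair)
  expect_identical(st$raster$bands$RBR, band(idx, "RBR"))
  # the visualization triple is extractable by name
  viz <- subset_bands(st$raster, c("NDVI", "RBR", "fstd_sub_PC1"))
  expect_equal(names(viz$bands), c("NDVI", "RBR", "fstd_sub_PC1"))
})

test_that("a missing SWIR band degrades to a flagged 17-band stack", {
  sc <- small_scene()
  four <- c("B", "G", "R", "NIR")
  pair <- scene_pair(subset_bands(sc$pre, four), subset_bands(sc$post, four))
  expect_warning(st <- compose_predictors(pair), "SWIR")
  expect_equal(nrow(st$band_meta), 17L)
  expect_false("RBR" %in% st$band_meta$name)
  expect_false(st$standard)
})

test_that("correlation pruning drops the lower-priority band of each pair", {
  set.seed(13)
  sc <- small_scene()
  st <- compose_predictors(scene_pair(sc$pre, sc$post))
  # duplicate band 1 into band 10's slot: band 10 must be flagged, band 1 kept
  st$raster$bands[[10]] <- st$raster$bands[[1]]
  pruned <- prune_correlated(st)
  expect_true(pruned$kept[1])
  expect_false(pruned$kept[10])
  # threshold 0: every later band correlates (|r| > 0) with band 1
  all_one <- prune_correlated(st, threshold = 0)
  expect_identical(unname(all_one$kept), c(TRUE, rep(FALSE, 17)))
})

test_that("independent noise bands all survive pruning at n = 10000", {
  set.seed(99)
  g <- tiny_grid(100, 100)
  bands <- lapply(1:18, function(i) matrix(rnorm(10000), 100, 100))
  names(bands) <- paste0("p", 1:18)
  st <- structure(list(
    raster = ts_raster(g, bands),
    band_meta = data.frame(name = names(bands), source = "noise",
                           component = NA, rank = 1:18),
    kept = setNames(rep(TRUE, 18), names(bands)), standard = TRUE),
    class = "ts_predictor_stack")
  pruned <- prune_correlated(st)
  expect_true(all(pruned$kept))
  # determinism
  expect_identical(prune_correlated(st)$kept, pruned$kept)
})
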