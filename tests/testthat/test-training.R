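test_that("candidate points exhaust a mask with exactly n forest cells", {
  g <- tiny_grid(25, 20)
  m <- matrix(0, 25, 20)
  m[seq_len(500)] <- 1
  mask <- ts_raster(g, list(forest = m))
  pts <- draw_candidate_points(mask, 500, seed = 1)
  expect_equal(nrow(pts), 500L)
  expect_setequal(pts$row + (pts$col - 1L) * 25L, which(m == 1))
  expect_error(draw_candidate_points(mask, 501, seed = 1), "forest cells")
})

test_that("the same seed reproduces the same points; seeds differ", {
  sc <- small_scene()
  a <- draw_candidate_points(sc$forest_mask, 100, seed = 5)
  b <- draw_candidate_points(sc$forest_mask, 100, seed = 5)
  expect_identical(a, b)
  c <- draw_candidate_points(sc$forest_mask, 100, seed = 6)
  expect_false(identical(a, c))
})

test_that("candidate points are uniform over the forest (quadrant chi-square)", {
  g <- tiny_grid(40, 40)
  mask <- ts_raster(g, list(forest = matrix(1, 40, 40)))
  rejections <- 0L
  for (seed in 1:100) {
    pts <- draw_candidate_points(mask, 200, seed = seed)
    quad <- 2L * (pts$row > 20) + (pts$col > 20) + 1L
    p <- chisq.test(tabulate(quad, 4))$p.value
    if (p < 0.01) rejections <- rejections + 1L
  }
  # under uniformity ~1 rejection is expected in 100 tests at alpha = 0.01
  expect_lte(rejections, 5L)
})

test_that("labels follow point-in-polygon membership", {
  truth <- rect_polyset(c(100, 100, 300, 250), type = "clearcut")
  pts <- data.frame(row = 1:4, col = 1:4,
                    x = c(200, 99, 305, 150), y = c(175, 175, 175, 249))
  lab <- label_points(pts, truth)
  expect_equal(lab$label, c(1L, 0L, 0L, 1L))
  # centroid of a polygon labels 1; empty truth labels everything 0
  empty <- ts_polyset(list(), data.frame())
  expect_true(all(label_points(pts, empty)$label == 0L))
})

test_that("edge-straddling points match an even-odd oracle", {
  sc <- small_scene()
  truth <- scene_to_training_truth(sc)
  set.seed(31)
  # points concentrated around the first polygon's bounding box
  ring <- truth$geometries[[1]][[1]]
  px <- runif(400, min(ring[, 1]) - 15, max(ring[, 1]) + 15)
  py <- runif(400, min(ring[, 2]) - 15, max(ring[, 2]) + 15)
  got <- points_in_polyset(px, py, truth)
  want <- vapply(seq_along(px), function(i) {
    any(vapply(truth$geometries, function(g) {
      crossings <- 0L
      for (r in g) for (k in seq_len(nrow(r) - 1L)) {
        y1 <- r[k, 2]; y2 <- r[k + 1, 2]
        if ((y1 > py[i]) != (y2 > py[i])) {
          xi <- r[k, 1] + (py[i] - y1) / (y2 - y1) * (r[k + 1, 1] - r[k, 1])
          if (px[i] < xi) crossings <- crossings + 1L
        }
      }
      crossings %% 2L == 1L
    }, NA))
  }, NA)
  expect_identical(got, want)
})

test_that("balancing adds ~214 treatment points to a 500-point all-zero sample", {
  sc <- small_scene()
  truth <- scene_to_training_truth(sc)
  g <- sc$pre$grid
  pts <- draw_candidate_points(sc$forest_mask, 500, seed = 7)
  pts$label <- 0L  # force the no-hit case
  out <- balance_training(pts, truth, g, seed = 8)
  added <- nrow(out) - 500L
  expect_equal(added, round(500 * 0.3 / 0.7))  # 214
  frac <- mean(out$label == 1L)
  expect_gte(frac, 0.28)
  expect_lte(frac, 0.32)
  expect_equal(sum(out$label == 0L), 500L)  # never deletes non-treatments
})

test_that("a sample already at or above the target ratio is returned unchanged", {
  pts <- data.frame(row = 1, col = 1, x = 5, y = 5)[rep(1, 100), ]
  pts$label <- rep(c(1L, 0L), c(35, 65))
  truth <- rect_polyset(c(0, 0, 50, 50))
  out <- balance_training(pts, truth, tiny_grid(), seed = 1)
  expect_identical(out, pts)
})

test_that("balancing fails when no treatment area exists", {
  pts <- data.frame(row = 1, col = 1, x = 5, y = 5, label = 0L)
  empty <- ts_polyset(list(), data.frame())
  expect_error(balance_training(pts, empty, tiny_grid(), seed = 1))
})

test_that("predictor extraction reads the containing cell exactly", {
  b <- small_model_bundle()
  stack <- b$stack
  g <- stack$raster$grid
  pts <- cell_centers(g, rows = c(20L, 60L), cols = c(30L, 50L))
  pts$label <- c(0L, 1L)
  got <- extract_predictors(pts, stack)
  for (bn in kept_bands(stack)) {
    expect_identical(got[[bn]], stack$raster$bands[[bn]][cbind(c(20L, 60L),
                                                              c(30L, 50L))])
  }
})

test_that("constant stacks give identical predictor vectors", {
  g <- tiny_grid(10, 10)
  st <- structure(list(
    raster = ts_raster(g, list(p1 = matrix(2, 10, 10),
                               p2 = matrix(-1, 10, 10))),
    band_meta = data.frame(name = c("p1", "p2"), source = "x",
                           component = NA, rank = 1:2),
    kept = c(p1 = TRUE, p2 = TRUE), standard = TRUE),
    class = "ts_predictor_stack")
  pts <- cell_centers(g, rows = c(1L, 5L, 9L), cols = c(1L, 5L, 9L))
  pts$label <- c(0L, 1L, 0L)
  out <- extract_predictors(pts, st)
  expect_equal(out$p1, rep(2, 3))
  expect_equal(out$p2, rep(-1, 3))
})

test_that("points on nodata are dropped with a count matching a mask query", {
  g <- tiny_grid(10, 10)
  p1 <- matrix(1.0, 10, 10)
  p1[3, ] <- NA  # a nodata stripe
  st <- structure(list(
    raster = ts_raster(g, list(p1 = p1)),
    band_meta = data.frame(name = "p1", source = "x", component = NA,
                           rank = 1),
    kept = c(p1 = TRUE), standard = TRUE),
    class = "ts_predictor_stack")
  rows <- c(1L, 3L, 3L, 7L)
  pts <- cell_centers(g, rows = rows, cols = c(2L, 4L, 9L, 1L))
  pts$label <- 0L
  expect_warning(out <- extract_predictors(pts, st), "dropped")
  expect_equal(nrow(out), sum(!is.na(p1[cbind(rows, c(2L, 4L, 9L, 1L))])))
  # all points on nodata is an error
  all_bad <- cell_centers(g, rows = c(3L, 3L), cols = c(1L, 2L))
  all_bad$label <- 0L
  expect_error(suppressWarnings(extract_predictors(all_bad, st)), "nodata")
})
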