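test_that("thresholding above the global maximum yields an empty set", {
  r <- ts_raster(tiny_grid(5, 5), list(v = matrix(0.4, 5, 5)))
  ps <- threshold_polygonize(r, 0.9)
  expect_equal(n_polygons(ps), 0L)
})

test_that("a 3x3 block of ones at 100 m cells polygonizes to 9 ha", {
  g <- ts_grid(0, 1000, 100, 10, 10)
  m <- matrix(0, 10, 10)
  m[4:6, 4:6] <- 1
  ps <- threshold_polygonize(ts_raster(g, list(v = m)), 0.5)
  expect_equal(n_polygons(ps), 1L)
  expect_equal(ps$attributes$area_ha, 9)
  expect_equal(ps$attributes$mean_vote, 1)
  expect_equal(ps$attributes$type, "candidate")
})

test_that("corner-touching blocks above threshold join under 8-connectivity", {
  g <- tiny_grid(10, 10)
  m <- matrix(0, 10, 10)
  m[2:3, 2:3] <- 0.9
  m[4:5, 4:5] <- 0.8
  ps <- threshold_polygonize(ts_raster(g, list(v = m)), 0.5)
  expect_equal(n_polygons(ps), 1L)
})

test_that("thresholding is strict: cells exactly at the cutoff stay out", {
  g <- tiny_grid(4, 4)
  m <- matrix(0.25, 4, 4)
  m[1, 1] <- 0.26
  ps <- threshold_polygonize(ts_raster(g, list(v = m)), 0.25)
  expect_equal(sum(ps$attributes$n_cells), 1L)
})

test_that("the filtering ledger removes slivers, burned and non-forest polygons", {
  g <- ts_grid(0, 2000, 10, 200, 200)
  m <- matrix(0, 200, 200)
  m[10:12, 10:12] <- 1      # 9 cells = 0.09 ha -> sliver
  m[50:61, 50:61] <- 1      # 144 cells = 1.44 ha, clean
  m[100:111, 100:111] <- 1  # clean
  m[150:161, 10:21] <- 1    # will overlap wildfire
  m[20:31, 150:161] <- 1    # will sit on non-forest
  cand <- threshold_polygonize(ts_raster(g, list(v = m)), 0.5)
  expect_equal(n_polygons(cand), 5L)
  wf <- rect_polyset(c(100, 380, 130, 420))  # overlaps the 150:161 block
  fmask <- matrix(1, 200, 200)
  fmask[, 140:200] <- 0
  res <- filter_polygons(cand, wf, ts_raster(g, list(f = fmask)))
  expect_equal(n_polygons(res$kept), 2L)
  expect_setequal(res$removed$attributes$removal_reason,
                  c("sliver", "wildfire_overlap", "nonforest"))
  # audit property: kept + removed reassemble the input
  expect_equal(n_polygons(res$kept) + n_polygons(res$removed),
               n_polygons(cand))
  expect_equal(sum(res$kept$attributes$area_ha) +
                 sum(res$removed$attributes$area_ha),
               sum(cand$attributes$area_ha))
})

test_that("a 0.9 ha polygon is removed as a sliver", {
  g <- tiny_grid(20, 20)
  m <- matrix(0, 20, 20)
  m[2:10, 2:11] <- 1  # 90 cells = 0.9 ha at 10 m
  cand <- threshold_polygonize(ts_raster(g, list(v = m)), 0.5)
  expect_equal(cand$attributes$area_ha, 0.9)
  res <- filter_polygons(cand, NULL, NULL)
  expect_equal(n_polygons(res$kept), 0L)
  expect_equal(res$removed$attributes$removal_reason, "sliver")
})

test_that("a single vertex touch with a wildfire perimeter counts as intersecting", {
  g <- tiny_grid(30, 30)
  m <- matrix(0, 30, 30)
  m[10:20, 10:20] <- 1  # polygon spans x 90..200, y 100..210
  cand <- threshold_polygonize(ts_raster(g, list(v = m)), 0.5)
  wf <- rect_polyset(c(200, 50, 260, 100))  # touches only at (200, 100)
  res <- filter_polygons(cand, wf, NULL)
  expect_equal(n_polygons(res$kept), 0L)
  expect_equal(res$removed$attributes$removal_reason, "wildfire_overlap")
})

test_that("user exclusion polygons remove with reason 'user'", {
  g <- tiny_grid(30, 30)
  m <- matrix(0, 30, 30)
  m[5:16, 5:16] <- 1
  cand <- threshold_polygonize(ts_raster(g, list(v = m)), 0.5)
  excl <- rect_polyset(c(60, 150, 120, 200))
  res <- filter_polygons(cand, NULL, NULL, exclusions = excl)
  expect_equal(res$removed$attributes$removal_reason, "user")
})

test_that("suggested thresholds sit below nearly all known-treatment values", {
  b <- small_model_bundle()
  seg <- mean_shift_segment(b$votes)
  segv <- segment_value_raster(seg)
  thr <- suggest_threshold(segv, b$truth)
  inb <- rasterize_polyset(b$truth, segv$grid) == 1
  vals <- segv$bands$segment_value[inb]
  vals <- vals[is.finite(vals)]
  expect_gte(mean(vals > thr), 0.9)
  expect_lt(thr, max(vals))
})

test_that("kernel density reproduces the quartic closed form at a point", {
  g <- ts_grid(0, 2000, 10, 200, 200)
  # one 100 m cell worth of treatment: a 10x10 block of 10 m cells
  ps <- rect_polyset(c(1000, 900, 1100, 1000))
  dens <- kernel_density(ps, g)
  dg <- dens$grid
  expect_equal(dg$cell_size, 100)
  # the treated cell's own center carries K(0) = 3 / (pi * 1 km^2)
  rc <- map_to_cell(dg, 1050, 950)
  expect_equal(dens$bands$density[rc$row, rc$col], 3 / pi,
               tolerance = 1e-9)
  # mass conservation: integral over the padded grid = 1 point
  mass <- sum(dens$bands$density) * (0.1 * 0.1)  # cell area in km^2
  expect_equal(mass, 1, tolerance = 0.005)
  # radial monotonicity along a row through the point
  row_vals <- dens$bands$density[rc$row, ]
  peak <- which.max(row_vals)
  expect_true(all(diff(row_vals[peak:length(row_vals)]) <= 1e-12))
  expect_true(all(diff(row_vals[1:peak]) >= -1e-12))
})

test_that("kernel density of an empty polygon set is a zero surface", {
  g <- ts_grid(0, 1000, 10, 100, 100)
  empty <- ts_polyset(list(), data.frame())
  dens <- kernel_density(empty, g)
  expect_true(all(dens$bands$density == 0))
})
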