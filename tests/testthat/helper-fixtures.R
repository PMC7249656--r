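# Shared fixtures. Scenes are generated once per test run and memoised.

tiny_grid <- function(n_rows = 10, n_cols = 10, cell_size = 10,
                      origin_x = 0, origin_y = n_rows * cell_size) {
  ts_grid(origin_x, origin_y, cell_size, n_rows, n_cols)
}

mk_raster <- function(..., grid = NULL) {
  bands <- list(...)
  if (is.null(grid)) grid <- tiny_grid(nrow(bands[[1]]), ncol(bands[[1]]))
  ts_raster(grid, bands)
}

rand_raster <- function(n_rows = 10, n_cols = 10, n_bands = 1, seed = 1) {
  set.seed(seed)
  bands <- lapply(seq_len(n_bands), function(i)
    matrix(rnorm(n_rows * n_cols), n_rows, n_cols))
  names(bands) <- paste0("b", seq_len(n_bands))
  ts_raster(tiny_grid(n_rows, n_cols), bands)
}

# Axis-aligned rectangle polygon set (closed CCW rings).
rect_polyset <- function(..., type = NULL) {
  rects <- list(...)
  geoms <- lapply(rects, function(r)  # r = c(x0, y0, x1, y1)
    list(cbind(c(r[1], r[3], r[3], r[1], r[1]),
               c(r[2], r[2], r[4], r[4], r[2]))))
  at <- data.frame(row.names = seq_along(geoms))
  if (!is.null(type)) at <- data.frame(type = rep(type, length(geoms)))
  ts_polyset(geoms, at)
}

# Small scene shared by module tests (cheaper than the default study scene).
.fixture_env <- new.env(parent = emptyenv())

small_scene <- function() {
  if (is.null(.fixture_env$scene))
    .fixture_env$scene <- generate_scene(scene_spec(
      seed = 11, n_rows = 120, n_cols = 120, n_clearcut = 2, n_thinning = 2,
      n_fire = 2, n_wildfire = 1, n_confuser = 2))
  .fixture_env$scene
}

# Predictor stack + trained model on the small scene, built once.
small_model_bundle <- function() {
  if (is.null(.fixture_env$bundle)) {
    sc <- small_scene()
    pair <- scene_pair(sc$pre, histogram_match(sc$post, sc$pre))
    st <- compose_predictors(pair, mask = sc$forest_mask$bands[[1]] == 1)
    st$raster <- apply_mask(st$raster, sc$forest_mask)
    stack <- prune_correlated(st)
    truth <- scene_to_training_truth(sc)
    pts <- label_points(draw_candidate_points(sc$forest_mask, 500, seed = 21),
                        truth)
    pts <- balance_training(pts, truth, sc$pre$grid, seed = 22)
    train <- extract_predictors(pts, stack)
    model <- fit_random_forest(train, rf_config(seed = 23))
    votes <- predict_vote_raster(model, stack)
    .fixture_env$bundle <- list(scene = sc, stack = stack, truth = truth,
                                train = train, model = model, votes = votes)
  }
  .fixture_env$bundle
}
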