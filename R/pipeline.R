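# End-to-end driver: preprocessing -> predictor stack -> training -> Random
# Forests -> segmentation -> polygons -> burned areas -> accuracy, with a
# reproducibility manifest.

#' Default pipeline configuration
#'
#' All numeric constants of the method appear here and are overridable:
#' the 0.75 correlation threshold, 500 training points at a 30% treatment
#' ratio, 100 trees at a 0.66 train ratio, segmentation details 20/10 with
#' minimum segment size 10, the 1 ha sliver threshold, accuracy thresholds
#' 0.25/0.5/0.75, 500 validation points per class, and the 100 m / 1 km
#' kernel-density parameters.
#'
#' @param seed Master seed; stage seeds are derived from it.
#' @return Named list of defaults.
#' @export
pipeline_defaults <- function(seed = 1L) {
  list(seed = as.integer(seed),
       correlation_threshold = 0.75,
       n_training_points = 500L, treatment_ratio = 0.30,
       ratio_tolerance = 0.02,
       n_trees = 100L, train_ratio = 0.66,
       spectral_detail = 20, spatial_detail = 10, min_segment_size = 10L,
       threshold = NULL,  # NULL: derive from known treatments
       threshold_quantile = 0.05,
       min_area_ha = 1,
       accuracy_thresholds = c(0.25, 0.5, 0.75),
       n_validation_per_class = 500L,
       density_cell_size = 100, density_radius = 1000,
       histogram_bins = 1024L)
}

#' Run the full treatment-detection pipeline
#'
#' Stages, in order: (A) scene simulation or input loading; (B) radiometric
#' harmonization (the post image histogram-matched to the pre image) and
#' forest masking; (C) the 18-band predictor stack with correlation pruning;
#' (D) training-sample construction from mechanical-treatment truth;
#' (E) Random Forests fitting with OOB metrics and the vote raster;
#' (F) mean-shift segmentation; (G) threshold polygonization and filtering;
#' (H) prescribed-fire polygons from burned-area rasters; (I) independent
#' accuracy assessment (error matrices at the three thresholds plus
#' ROC/AUC) and the kernel-density surface. Re-running with the same
#' configuration reproduces every output.
#'
#' @param config A list: either `scene` (a [scene_spec()]) for simulation,
#'   or `inputs` (named paths `pre`, `post`, `forest_mask`, `truth`,
#'   `perimeters`, and optionally `burned`, a vector) to load from disk.
#'   Remaining entries override [pipeline_defaults()]. May also be a path to
#'   a YAML/JSON file with these entries (a `scene` block becomes a
#'   [scene_spec()]).
#' @param out_dir Optional directory; when given, all artifacts plus a
#'   `manifest.json` (parameters, seeds, file hashes) are written there.
#' @return An object of class `ts_pipeline_result`: list with the scene,
#'   stack, model, votes, segments, threshold, polygon sets, accuracy
#'   reports, ROC and density surface.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1L)
    config <- .read_config(config)
  cfg <- utils::modifyList(pipeline_defaults(config$seed %||% 1L), config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  # A: scene
  scene <- stage("load", {
    if (!is.null(cfg$scene)) {
      sc <- cfg$scene
      if (!inherits(sc, "scene_spec")) sc <- do.call(scene_spec, sc)
      generate_scene(sc)
    } else if (!is.null(cfg$inputs)) {
      .load_scene_inputs(cfg$inputs)
    } else stop("config must name a scene spec or input paths")
  })
  grid <- scene$pre$grid
  if (is_geographic_crs(grid$crs_id))
    stop("geographic CRS ", grid$crs_id,
         " not supported: area thresholds require projected meters")
  if (is.null(scene$forest_mask)) stop("missing forest mask input")

  # B: preprocess
  prep <- stage("preprocess", {
    post_m <- histogram_match(scene$post, scene$pre, cfg$histogram_bins)
    list(pair = scene_pair(scene$pre, post_m),
         fmask = scene$forest_mask$bands[[1]] == 1)
  })

  # C: features
  stack <- stage("features", {
    st <- compose_predictors(prep$pair, mask = prep$fmask)
    masked <- apply_mask(st$raster, scene$forest_mask)
    st$raster <- masked
    prune_correlated(st, cfg$correlation_threshold)
  })

  # D: training
  truth_mech <- scene_to_training_truth(scene)
  train <- stage("training", {
    pts <- draw_candidate_points(scene$forest_mask, cfg$n_training_points,
                                 seed = cfg$seed + 1L)
    pts <- label_points(pts, truth_mech)
    pts <- balance_training(pts, truth_mech, grid,
                            target_ratio = cfg$treatment_ratio,
                            tolerance = cfg$ratio_tolerance,
                            seed = cfg$seed + 2L)
    extract_predictors(pts, stack)
  })

  # E: classify
  model <- stage("classify", fit_random_forest(
    train, rf_config(n_trees = cfg$n_trees, train_ratio = cfg$train_ratio,
                     seed = cfg$seed + 3L)))
  votes <- stage("classify", predict_vote_raster(model, stack))

  # F: segment
  seg <- stage("segment", mean_shift_segment(
    votes, cfg$spectral_detail, cfg$spatial_detail, cfg$min_segment_size))
  segvals <- segment_value_raster(seg)

  # G: polygons
  threshold <- cfg$threshold %||%
    stage("polygons", suggest_threshold(segvals, truth_mech,
                                        cfg$threshold_quantile))
  polys <- stage("polygons", {
    cand <- threshold_polygonize(segvals, threshold)
    filter_polygons(cand, scene$wildfire_perimeters, scene$forest_mask,
                    cfg$min_area_ha)
  })

  # H: burned areas
  fire <- if (length(scene$burned_area_rasters) > 0L) stage("burned", {
    merged <- merge_burned(scene$burned_area_rasters)
    prescribed_fire_polygons(merged, scene$wildfire_perimeters,
                             scene$forest_mask, cfg$min_area_ha)
  }) else NULL

  # I: accuracy + density
  assess <- stage("accuracy", {
    val <- sample_validation(truth_mech, grid, scene$forest_mask,
                             cfg$n_validation_per_class,
                             seed = cfg$seed + 4L)
    reports <- lapply(cfg$accuracy_thresholds, function(th)
      accuracy_report(contingency(binarize_votes(votes, th), val)))
    names(reports) <- paste0("t", cfg$accuracy_thresholds)
    rc <- map_to_cell(grid, val$x, val$y)
    scores <- band(votes, "treatment")[cbind(rc$row, rc$col)]
    list(samples = val, reports = reports,
         roc = roc_auc(scores, val$label))
  })
  density <- stage("density", kernel_density(
    polys$kept, grid, cfg$density_cell_size, cfg$density_radius))

  result <- structure(list(
    config = cfg, scene = scene, stack = stack, training = train,
    model = model, votes = votes, segments = seg,
    segment_values = segvals, threshold = threshold,
    treatment_polygons = polys$kept, removed_polygons = polys$removed,
    prescribed_fire = fire, accuracy = assess, density = density),
    class = "ts_pipeline_result")
  if (!is.null(out_dir)) .write_run_dir(result, out_dir)
  result
}

#' @export
print.ts_pipeline_result <- function(x, ...) {
  m <- x$model$metrics
  cat(sprintf(paste0(
    "<ts_pipeline_result>\n",
    "  predictors kept: %d of %d; OOB class error %.3f (rmse %.3f)\n",
    "  segments: %d; threshold %.3f -> %d treatment polygon(s) kept, %d removed\n",
    "  prescribed fire polygon(s): %s; validation AUC %.4f\n"),
    sum(x$stack$kept), length(x$stack$kept),
    m["oob_rel_class_error"], m["oob_rmse"],
    length(x$segments$segment_sizes), x$threshold,
    n_polygons(x$treatment_polygons), n_polygons(x$removed_polygons),
    if (is.null(x$prescribed_fire)) "-" else
      n_polygons(x$prescribed_fire$kept),
    x$accuracy$roc$auc))
  invisible(x)
}

.read_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path) else jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!is.null(cfg$scene)) cfg$scene <- do.call(scene_spec, cfg$scene)
  cfg
}

.load_scene_inputs <- function(inputs) {
  need <- c("pre", "post", "forest_mask", "truth", "perimeters")
  missing <- setdiff(need, names(inputs))
  if (length(missing))
    stop("missing input path(s): ", paste(missing, collapse = ", "))
  pre <- read_raster(inputs$pre); post <- read_raster(inputs$post)
  fmask <- read_raster(inputs$forest_mask)
  assert_same_grid(pre, post); assert_same_grid(pre, fmask)
  burned <- lapply(inputs$burned %||% character(0), read_raster)
  structure(list(pre = pre, post = post, forest_mask = fmask,
                 treatments = read_polygons(inputs$truth),
                 wildfire_perimeters = read_polygons(inputs$perimeters),
                 burned_area_rasters = burned, spec = NULL),
            class = "scene_truth")
}

.write_run_dir <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  crs <- result$votes$grid$crs_id
  write_raster(result$votes, file.path(out_dir, "votes.tif"))
  write_raster(result$segment_values, file.path(out_dir, "segment_values.tif"))
  write_raster(result$density, file.path(out_dir, "treatment_density.tif"))
  write_polygons(result$treatment_polygons,
                 file.path(out_dir, "treatments.geojson"), crs)
  write_polygons(result$removed_polygons,
                 file.path(out_dir, "removed.geojson"), crs)
  if (!is.null(result$prescribed_fire))
    write_polygons(result$prescribed_fire$kept,
                   file.path(out_dir, "prescribed_fire.geojson"), crs)
  acc <- lapply(result$accuracy$reports, function(r)
    r[c("overall", "ste", "user_acc_1", "user_acc_0", "producer_acc_1",
        "producer_acc_0", "chi_square", "df", "p_value")])
  report <- list(
    oob = as.list(result$model$metrics),
    accuracy = acc, auc = result$accuracy$roc$auc,
    threshold = result$threshold,
    kept_predictors = kept_bands(result$stack),
    n_treatment_polygons = n_polygons(result$treatment_polygons))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- setdiff(list.files(out_dir), "manifest.json")
  cfg <- result$config
  cfg$scene <- if (!is.null(cfg$scene)) unclass(cfg$scene) else NULL
  manifest <- list(
    package_version = tryCatch(
      as.character(utils::packageVersion("treatscan")),
      error = function(e) "dev"),
    seed = cfg$seed,
    parameters = cfg[setdiff(names(cfg), "inputs")],
    files = as.list(tools::md5sum(file.path(out_dir, files))))
  names(manifest$files) <- files
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
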