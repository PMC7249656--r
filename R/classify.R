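# Random Forests treatment classification: fixed-ratio per-tree subsampling,
# out-of-bag error metrics, and the weighted-vote two-band proportion raster.
#
# Tree induction is delegated to ranger, configured away from its defaults to
# the regime this module contracts: each of the 100 trees trains on an
# independent 66% subsample drawn WITHOUT replacement (not a bootstrap), with
# floor(sqrt(p)) candidate predictors per split. The out-of-bag bookkeeping,
# the three error metrics and the vote-proportion surfaces are computed here
# from ranger's per-tree inbag counts and per-tree predictions.

#' Random Forests configuration
#'
#' @param n_trees Number of trees (default 100).
#' @param train_ratio Fraction of samples each tree trains on, drawn without
#'   replacement (default 0.66; the remaining 34% are that tree's out-of-bag
#'   set).
#' @param m_try Predictors tried per split; default `NULL` means
#'   `floor(sqrt(p))` over the kept predictors at fit time.
#' @param seed Integer seed making the ensemble deterministic.
#' @return An object of class `rf_config`.
#' @export
rf_config <- function(n_trees = 100L, train_ratio = 0.66, m_try = NULL,
                      seed = 1L) {
  stopifnot(n_trees >= 1, train_ratio > 0, train_ratio < 1,
            is.null(m_try) || m_try >= 1)
  structure(list(n_trees = as.integer(n_trees), train_ratio = train_ratio,
                 m_try = m_try, seed = as.integer(seed)),
            class = "rf_config")
}

#' Fit the treatment classification forest
#'
#' @param train A [extract_predictors()] training set with both labels
#'   present.
#' @param config An [rf_config()].
#' @return An object of class `ts_rf_model` with fields `fit` (the ranger
#'   ensemble), `config`, `predictor_bands`, `m_try`, `oob` (per-sample OOB
#'   vote fractions and tree counts) and `metrics`
#'   (`oob_rmse`, `oob_avg_rel_error`, `oob_rel_class_error`).
#' @export
fit_random_forest <- function(train, config = rf_config()) {
  bands <- attr(train, "predictor_bands")
  if (is.null(bands)) bands <- setdiff(names(train), c("x", "y", "label"))
  y <- train$label
  if (length(unique(y)) < 2L)
    stop("training set must contain both labels")
  p <- length(bands)
  m_try <- if (is.null(config$m_try)) max(1L, floor(sqrt(p))) else config$m_try
  d <- data.frame(label = factor(y, levels = c(0L, 1L)),
                  train[, bands, drop = FALSE])
  fit <- ranger::ranger(
    label ~ ., data = d,
    num.trees = config$n_trees, mtry = m_try,
    replace = FALSE, sample.fraction = config$train_ratio,
    keep.inbag = TRUE, seed = config$seed, num.threads = 1)
  inbag <- do.call(cbind, fit$inbag.counts)        # samples x trees
  pred_all <- stats::predict(fit, d, predict.all = TRUE,
                             num.threads = 1)$predictions  # 1/2 class index
  oob_mask <- inbag == 0L
  n_oob <- rowSums(oob_mask)
  if (any(n_oob == 0L))
    warning(sum(n_oob == 0L), " sample(s) never out-of-bag; ",
            "their OOB vote is undefined")
  vote1 <- rowSums((pred_all == 2L) & oob_mask)
  p_oob <- ifelse(n_oob > 0L, vote1 / n_oob, NA_real_)
  metrics <- oob_metrics(p_oob, y)
  structure(list(fit = fit, config = config, predictor_bands = bands,
                 m_try = m_try,
                 oob = data.frame(label = y, vote_fraction = p_oob,
                                  n_oob_trees = n_oob),
                 metrics = metrics),
            class = "ts_rf_model")
}

#' @export
print.ts_rf_model <- function(x, ...) {
  cat(sprintf(paste0("<ts_rf_model> %d trees, mtry %d over %d predictors\n",
                     "  OOB: rmse %.3f, avg rel error %.3f, class error %.3f\n"),
              x$config$n_trees, x$m_try, length(x$predictor_bands),
              x$metrics["oob_rmse"], x$metrics["oob_avg_rel_error"],
              x$metrics["oob_rel_class_error"]))
  invisible(x)
}

#' Out-of-bag error metrics
#'
#' For sample `i` with OOB treatment-vote fraction `p_i` and true label
#' `y_i`, let `q_i = p_i` if `y_i = 1` and `1 - p_i` otherwise (the OOB vote
#' share of the correct class). Then:
#' \itemize{
#'   \item `oob_rmse = sqrt(mean((1 - q_i)^2))` — error estimating the
#'     posterior probability of the correct class;
#'   \item `oob_avg_rel_error = mean(1 - q_i)`;
#'   \item `oob_rel_class_error` — fraction of incorrectly classified
#'     samples; a tied vote (`q_i = 0.5`) counts as an error for label 1
#'     (ties classify as non-treatment).
#' }
#'
#' @param p_oob Per-sample OOB treatment-vote fractions.
#' @param labels True 0/1 labels.
#' @return Named numeric vector of the three metrics (all in `[0, 1]`),
#'   computed over samples with a defined OOB vote.
#' @export
oob_metrics <- function(p_oob, labels) {
  ok <- !is.na(p_oob)
  p <- p_oob[ok]; y <- labels[ok]
  q <- ifelse(y == 1L, p, 1 - p)
  err <- q < 0.5 | (q == 0.5 & y == 1L)
  c(oob_rmse = sqrt(mean((1 - q)^2)),
    oob_avg_rel_error = mean(1 - q),
    oob_rel_class_error = mean(err))
}

#' Predict the two-band vote-proportion raster
#'
#' Per cell, band 2 (`treatment`) is the fraction of trees predicting label
#' 1 and band 1 (`non_treatment`) its complement, so the two bands sum to 1
#' at every finite cell. Cells with nodata in any kept predictor stay nodata.
#'
#' @param model A [fit_random_forest()] model.
#' @param stack A [compose_predictors()] stack whose kept bands match the
#'   model's predictors.
#' @param block_cells Cells predicted per batch (memory control).
#' @return A two-band [ts_raster()] (`non_treatment`, `treatment`).
#' @export
predict_vote_raster <- function(model, stack, block_cells = 200000L) {
  bands <- model$predictor_bands
  missing <- setdiff(bands, names(stack$raster$bands))
  if (length(missing))
    stop("stack lacks predictor band(s): ", paste(missing, collapse = ", "))
  g <- stack$raster$grid
  X <- sapply(bands, function(bn) as.vector(stack$raster$bands[[bn]]))
  X <- matrix(X, ncol = length(bands), dimnames = list(NULL, bands))
  ok <- which(rowSums(is.na(X)) == 0L)
  treat <- rep(NA_real_, nrow(X))
  if (length(ok)) for (start in seq(1L, length(ok), by = block_cells)) {
    idx <- ok[start:min(start + block_cells - 1L, length(ok))]
    nd <- as.data.frame(X[idx, , drop = FALSE])
    pr <- stats::predict(model$fit, nd, predict.all = TRUE,
                         num.threads = 1)$predictions
    treat[idx] <- rowMeans(pr == 2L)
  }
  ts_raster(g, list(
    non_treatment = matrix(1 - treat, g$n_rows, g$n_cols),
    treatment = matrix(treat, g$n_rows, g$n_cols)))
}
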