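# Independent accuracy assessment: binarization at fixed thresholds, the 2x2
# error matrix with its statistic set, and ROC/AUC.

#' Binarize a vote raster at a threshold
#'
#' Cells with treatment-vote proportion strictly greater than the threshold
#' become 1 (treatment), the rest 0; nodata propagates. The conventional
#' thresholds are 0.25, 0.5 and 0.75.
#'
#' @param votes A [predict_vote_raster()] result (band `treatment` is used),
#'   or any raster whose last band holds the vote proportion.
#' @param threshold Value in `[0, 1]`.
#' @return A one-band binary [ts_raster()] (`modeled`).
#' @export
binarize_votes <- function(votes, threshold) {
  if (!is.numeric(threshold) || threshold < 0 || threshold > 1)
    stop("threshold must lie in [0, 1]")
  v <- if ("treatment" %in% names(votes$bands)) band(votes, "treatment")
       else votes$bands[[length(votes$bands)]]
  out <- matrix(NA_real_, nrow(v), ncol(v))
  out[!is.na(v)] <- as.numeric(v[!is.na(v)] > threshold)
  ts_raster(votes$grid, list(modeled = out))
}

#' Draw a stratified validation sample
#'
#' `n_per_class` points uniformly over cells inside the truth polygons
#' (label 1) and `n_per_class` over cells outside them (label 0), both
#' restricted to the mask when given. Points are cell centers; reproducible
#' under `seed`.
#'
#' @param truth A [ts_polyset()] of treatment polygons.
#' @param grid The [ts_grid()] to sample on.
#' @param mask Optional one-band binary [ts_raster()] restricting both
#'   strata (e.g. forest cells).
#' @param n_per_class Points per stratum (default 500).
#' @param seed Integer seed.
#' @return Data frame with columns `row`, `col`, `x`, `y`, `label`.
#' @export
sample_validation <- function(truth, grid, mask = NULL, n_per_class = 500L,
                              seed = 1L) {
  inside <- rasterize_polyset(truth, grid) == 1
  ok <- matrix(TRUE, grid$n_rows, grid$n_cols)
  if (!is.null(mask)) {
    m <- mask$bands[[1]]
    ok <- !is.na(m) & m == 1
  }
  cells1 <- which(inside & ok)
  cells0 <- which(!inside & ok)
  if (length(cells1) < n_per_class)
    stop("truth polygons contain only ", length(cells1),
         " cells; need ", n_per_class)
  if (length(cells0) < n_per_class)
    stop("non-treatment area contains only ", length(cells0),
         " cells; need ", n_per_class)
  set.seed(seed)
  pick <- function(cells, label) {
    sel <- if (length(cells) == n_per_class) cells
           else sample(cells, n_per_class)
    rc <- arrayInd(sel, c(grid$n_rows, grid$n_cols))
    out <- cell_centers(grid, rows = rc[, 1], cols = rc[, 2])
    out$label <- label
    out
  }
  rbind(pick(cells1, 1L), pick(cells0, 0L))
}

#' Build the 2x2 contingency table
#'
#' Counts `a` (modeled 1, true 1), `b` (modeled 1, true 0), `c` (modeled 0,
#' true 1) and `d` (modeled 0, true 0) over the sample locations; points on
#' nodata cells are dropped.
#'
#' @param modeled One-band binary [ts_raster()], e.g. from
#'   [binarize_votes()].
#' @param samples Labeled locations from [sample_validation()].
#' @return An object of class `ts_contingency`: list with `a`, `b`, `c`,
#'   `d`, `n`.
#' @export
contingency <- function(modeled, samples) {
  g <- modeled$grid
  rc <- map_to_cell(g, samples$x, samples$y)
  if (anyNA(rc$row)) stop("some sample points fall outside the grid")
  m <- modeled$bands[[1]][cbind(rc$row, rc$col)]
  ok <- !is.na(m)
  m <- m[ok]; y <- samples$label[ok]
  tab <- list(a = sum(m == 1 & y == 1), b = sum(m == 1 & y == 0),
              c = sum(m == 0 & y == 1), d = sum(m == 0 & y == 0))
  tab$n <- tab$a + tab$b + tab$c + tab$d
  structure(tab, class = "ts_contingency")
}

#' Construct a contingency table from counts
#' @param a,b,c,d Cell counts: modeled 1/true 1, modeled 1/true 0,
#'   modeled 0/true 1, modeled 0/true 0.
#' @return A `ts_contingency` object.
#' @export
contingency_counts <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0, a + b + c + d > 0)
  structure(list(a = a, b = b, c = c, d = d, n = a + b + c + d),
            class = "ts_contingency")
}

#' Accuracy statistics of a 2x2 error matrix
#'
#' Computes overall accuracy `(a + d) / n` with its binomial standard error,
#' user accuracies (per modeled class, as percentages), producer accuracies
#' (per true class, as percentages), and the uncorrected chi-square statistic
#' `n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))` with 1 degree of freedom (no
#' continuity correction) and its p-value. A zero marginal leaves the
#' chi-square undefined (`NA`).
#'
#' @param t A `ts_contingency` table.
#' @return An object of class `ts_accuracy_report`: list with fields
#'   `overall`, `ste`, `user_acc_1`, `user_acc_0`, `producer_acc_1`,
#'   `producer_acc_0` (percentages), `chi_square`, `df`, `p_value`, `table`.
#' @export
accuracy_report <- function(t) {
  stopifnot(inherits(t, "ts_contingency"))
  a <- t$a; b <- t$b; c <- t$c; d <- t$d; n <- t$n
  marg <- c(a + b, c + d, a + c, b + d)
  chi <- if (any(marg == 0)) NA_real_ else
    n * (a * d - b * c)^2 / prod(marg)
  overall <- (a + d) / n
  pct <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  structure(list(
    overall = overall,
    ste = sqrt(overall * (1 - overall) / n),
    user_acc_1 = pct(a, a + b), user_acc_0 = pct(d, c + d),
    producer_acc_1 = pct(a, a + c), producer_acc_0 = pct(d, b + d),
    chi_square = chi, df = 1L,
    p_value = if (is.na(chi)) NA_real_ else
      stats::pchisq(chi, df = 1, lower.tail = FALSE),
    table = t), class = "ts_accuracy_report")
}

#' @export
print.ts_accuracy_report <- function(x, ...) {
  t <- x$table
  cat(sprintf(paste0(
    "2 x 2 accuracy assessment (n = %d)\n",
    "                  true 1   true 0   user acc\n",
    "  modeled 1     %7d  %7d      %5.1f\n",
    "  modeled 0     %7d  %7d      %5.1f\n",
    "  producer acc    %5.1f    %5.1f\n",
    "  overall %.3f (STE %.4f); chi-square %s, df 1, p %s\n"),
    t$n, t$a, t$b, x$user_acc_1, t$c, t$d, x$user_acc_0,
    x$producer_acc_1, x$producer_acc_0, x$overall, x$ste,
    if (is.na(x$chi_square)) "undefined" else sprintf("%.2f", x$chi_square),
    if (is.na(x$p_value)) "-" else format(x$p_value, digits = 3)))
  invisible(x)
}

#' ROC curve and AUC from scores
#'
#' Sweeps every distinct score as a threshold (ties grouped into one step),
#' records the true- and false-positive rates, and integrates by the
#' trapezoidal rule — equivalent to the Mann-Whitney U statistic with ties
#' counted one half.
#'
#' @param scores Numeric vote proportions (higher = more treatment-like).
#' @param labels True 0/1 labels; both classes must be present.
#' @return An object of class `ts_roc`: list with `thresholds` (descending),
#'   `tpr`, `fpr` (curve points from (0,0) to (1,1)) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(y == 1); fp <- cumsum(y == 0)
  last <- !duplicated(grp, fromLast = TRUE)
  tpr <- c(0, tp[last] / n1); fpr <- c(0, fp[last] / n0)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(thresholds = c(Inf, s[last]), tpr = tpr, fpr = fpr,
                 auc = auc), class = "ts_roc")
}

#' @export
print.ts_roc <- function(x, ...) {
  cat(sprintf("<ts_roc> %d threshold steps, AUC = %.4f\n",
              length(x$thresholds) - 1L, x$auc))
  invisible(x)
}
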