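# The nine printed count matrices of the study's error-matrix tables
# (threshold, a, b, c, d and the published statistics) are exercised in
# test-acceptance.R; unit behavior is covered here.

test_that("binarization is strict and monotone in the threshold", {
  g <- tiny_grid(6, 6)
  set.seed(2)
  v <- matrix(runif(36), 6, 6)
  v[2, 2] <- 0.25  # exactly at the cutoff
  v[3, 3] <- NA
  votes <- ts_raster(g, list(non_treatment = 1 - v, treatment = v))
  b25 <- binarize_votes(votes, 0.25)$bands$modeled
  expect_equal(b25[2, 2], 0)           # "higher than" is strict
  expect_true(is.na(b25[3, 3]))
  expect_true(all(binarize_votes(votes, 0)$bands$modeled[!is.na(v)] ==
                    (v[!is.na(v)] > 0)))
  counts <- sapply(c(0.25, 0.5, 0.75), function(th)
    sum(binarize_votes(votes, th)$bands$modeled, na.rm = TRUE))
  expect_true(all(diff(counts) <= 0))
  expect_error(binarize_votes(votes, 1.2), "threshold")
})

test_that("validation sampling is stratified, reproducible and inside polygons", {
  sc <- small_scene()
  truth <- scene_to_training_truth(sc)
  s <- sample_validation(truth, sc$pre$grid, sc$forest_mask,
                         n_per_class = 150, seed = 3)
  expect_equal(nrow(s), 300L)
  expect_equal(sum(s$label == 1), 150L)
  inside <- points_in_polyset(s$x, s$y, truth)
  expect_true(all(inside[s$label == 1]))
  expect_true(all(!inside[s$label == 0]))
  expect_identical(s, sample_validation(truth, sc$pre$grid, sc$forest_mask,
                                        n_per_class = 150, seed = 3))
  expect_error(sample_validation(truth, sc$pre$grid, sc$forest_mask,
                                 n_per_class = 1e6, seed = 1), "cells")
})

test_that("contingency counting matches a brute-force point loop", {
  set.seed(8)
  g <- tiny_grid(40, 40)
  m <- matrix(rbinom(1600, 1, 0.4), 40, 40)
  m[sample(1600, 30)] <- NA
  modeled <- ts_raster(g, list(modeled = m))
  rows <- sample(40, 1000, replace = TRUE)
  cols <- sample(40, 1000, replace = TRUE)
  samples <- cell_centers(g, rows = rows, cols = cols)
  samples$label <- rbinom(1000, 1, 0.5)
  t <- contingency(modeled, samples)
  # oracle: explicit loop
  a <- b <- c <- d <- 0L
  for (i in 1:1000) {
    mv <- m[rows[i], cols[i]]
    if (is.na(mv)) next
    if (mv == 1 && samples$label[i] == 1) a <- a + 1L
    else if (mv == 1) b <- b + 1L
    else if (samples$label[i] == 1) c <- c + 1L
    else d <- d + 1L
  }
  expect_equal(unclass(t)[c("a", "b", "c", "d")],
               list(a = a, b = b, c = c, d = d))
  expect_equal(t$n, a + b + c + d)
})

test_that("degenerate contingency tables behave as contracted", {
  # modeled identical to truth: no off-diagonal counts
  g <- tiny_grid(10, 10)
  m <- matrix(rep(c(1, 0), each = 50), 10, 10)
  modeled <- ts_raster(g, list(modeled = m))
  s <- cell_centers(g)
  s$label <- as.vector(m)
  t <- contingency(modeled, s)
  expect_equal(c(t$b, t$c), c(0L, 0L))
  r <- accuracy_report(t)
  expect_equal(r$overall, 1)
  expect_equal(r$user_acc_1, 100)
  expect_equal(r$user_acc_0, 100)
  # all-zero model: a = b = 0, chi-square undefined
  t0 <- contingency(ts_raster(g, list(modeled = matrix(0, 10, 10))), s)
  expect_equal(c(t0$a, t0$b), c(0L, 0L))
  r0 <- accuracy_report(t0)
  expect_true(is.na(r0$chi_square))
})

test_that("the chi-square closed form equals the expected-count brute force", {
  set.seed(12)
  for (i in 1:20) {
    cnt <- as.list(rmultinom(1, 500, c(0.3, 0.1, 0.15, 0.45))[, 1] + 1L)
    names(cnt) <- c("a", "b", "c", "d")
    t <- do.call(contingency_counts, cnt)
    r <- accuracy_report(t)
    O <- matrix(c(t$a, t$b, t$c, t$d), 2, byrow = TRUE)
    E <- outer(rowSums(O), colSums(O)) / sum(O)
    expect_equal(r$chi_square, sum((O - E)^2 / E), tolerance = 1e-12)
    expect_equal(r$p_value, pchisq(r$chi_square, 1, lower.tail = FALSE))
    expect_equal(r$ste, sqrt(r$overall * (1 - r$overall) / t$n))
  }
})

test_that("ROC handles separation, ties and the Mann-Whitney oracle", {
  sep <- roc_auc(c(0.9, 0.8, 0.7, 0.2, 0.1), c(1, 1, 1, 0, 0))
  expect_equal(sep$auc, 1)
  flat <- roc_auc(rep(0.5, 10), rep(c(1, 0), 5))
  expect_equal(flat$auc, 0.5)
  set.seed(19)
  scores <- round(runif(200), 2)  # rounding forces ties
  labels <- rbinom(200, 1, plogis(4 * scores - 2))
  if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
  r <- roc_auc(scores, labels)
  # U-statistic oracle with ties counted one half
  s1 <- scores[labels == 1]; s0 <- scores[labels == 0]
  u <- 0
  for (x in s1) u <- u + sum(x > s0) + 0.5 * sum(x == s0)
  expect_equal(r$auc, u / (length(s1) * length(s0)), tolerance = 1e-12)
  # curve anchored at (0,0) and (1,1), coordinates monotone
  expect_equal(c(r$tpr[1], r$fpr[1]), c(0, 0))
  expect_equal(c(r$tpr[length(r$tpr)], r$fpr[length(r$fpr)]), c(1, 1))
  expect_true(all(diff(r$tpr) >= 0) && all(diff(r$fpr) >= 0))
  # complement symmetry
  expect_equal(r$auc, 1 - roc_auc(-scores, labels)$auc, tolerance = 1e-12)
  expect_error(roc_auc(scores, rep(1, 200)), "both classes")
})

test_that("AUC agrees with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(23)
  scores <- runif(300)
  labels <- rbinom(300, 1, plogis(3 * scores - 1.5))
  if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
  ours <- roc_auc(scores, labels)$auc
  ref <- suppressMessages(as.numeric(pROC::auc(labels, scores)))
  expect_equal(ours, ref, tolerance = 1e-10)
})

test_that("producer accuracies shift monotonically with the threshold", {
  b <- small_model_bundle()
  sc <- b$scene
  truth <- b$truth
  val <- sample_validation(truth, sc$pre$grid, sc$forest_mask,
                           n_per_class = 200, seed = 9)
  reports <- lapply(c(0.25, 0.5, 0.75), function(th)
    accuracy_report(contingency(binarize_votes(b$votes, th), val)))
  p1 <- sapply(reports, `[[`, "producer_acc_1")
  p0 <- sapply(reports, `[[`, "producer_acc_0")
  expect_true(all(diff(p1) <= 1e-9))
  expect_true(all(diff(p0) >= -1e-9))
})
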