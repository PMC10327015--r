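test_that("learning features follow their definitions", {
  tmat <- rbind(a = c(50, 52, 54, 56, 58, 60),
                b = rep(50, 6),
                c = c(60, 58, 56, 54, 52, 50))
  lp <- learning_params(tmat)
  expect_equal(lp$avg_learning_rate, c(2, 0, -2))
  expect_equal(lp$initial_performance[1], 51)
  expect_equal(lp$final_performance[1], 60)
  expect_equal(lp$early_rise[1], 4)
  expect_equal(lp$late_rise[1], 4)
  expect_equal(lp$avg_performance[1], 55)
})

test_that("average learning rate telescopes to (t6 - t1)/5 for any curve", {
  set.seed(31)
  tmat <- matrix(rnorm(200 * 6, 50, 10), 200, 6)
  lp <- learning_params(tmat)
  expect_equal(lp$avg_learning_rate, (tmat[, 6] - tmat[, 1]) / 5)
  # incomplete series are excluded with a message
  tmat[3, 4] <- NA
  expect_message(lp2 <- learning_params(tmat), "excluding 1")
  expect_equal(nrow(lp2), 199L)
})

test_that("min-max normalization spans [0,1] and drops constant columns", {
  m <- cbind(a = c(2, 4, 6), b = c(0, 0.5, 1), k = c(3, 3, 3))
  expect_warning(out <- minmax_normalize(m), "constant")
  expect_equal(colnames(out), c("a", "b"))
  expect_equal(out[, "a"], c(0, 0.5, 1), ignore_attr = TRUE)
  expect_equal(out[, "b"], c(0, 0.5, 1), ignore_attr = TRUE)
  expect_equal(minmax_normalize(out), out)    # idempotent on [0,1] columns
  expect_error(minmax_normalize(matrix(nrow = 0, ncol = 0)), "empty")
})

test_that("PCA wrapper returns orthonormal loadings and full variance", {
  set.seed(8)
  x <- rnorm(100)
  collinear <- cbind(x = x, y = 2 * x + rnorm(100, sd = 1e-4))
  p <- pca_features(collinear, 2)
  expect_gte(p$explained_variance[1] / sum(p$explained_variance), 0.9999)

  m <- matrix(rnorm(100 * 8), 100, 8)
  p <- pca_features(m, 8)
  expect_equal(crossprod(p$loadings), diag(8), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(sum(p$explained_variance), sum(apply(m, 2, var)),
               tolerance = 1e-8)
  expect_true(all(diff(p$explained_variance) <= 1e-12))
  # exact reconstruction from all components
  centered <- sweep(m, 2, colMeans(m))
  expect_equal(p$scores %*% t(p$loadings[, 1:8]), centered,
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_error(pca_features(matrix(1, 5, 3)), "rank-0")
})

test_that("DBSCAN separates well-spaced planted blobs", {
  set.seed(5)
  pts <- rbind(matrix(rnorm(500 * 2, 0, 1), ncol = 2),
               matrix(rnorm(500 * 2, 10, 1), ncol = 2))
  eps <- choose_eps(pts, 10)
  labs <- dbscan_cluster(pts, eps, 10)
  expect_equal(length(setdiff(unique(labs), 0L)), 2L)
  expect_gte(mean(labs != 0L), 0.99)
  # the two blobs map to the two clusters
  expect_equal(length(unique(labs[1:500][labs[1:500] != 0])), 1L)
  expect_equal(length(unique(labs[501:1000][labs[501:1000] != 0])), 1L)
})

test_that("DBSCAN semantics match an independent graph oracle", {
  for (s in 1:5) {
    set.seed(100 + s)
    pts <- rbind(matrix(rnorm(60 * 2), ncol = 2),
                 matrix(rnorm(40 * 2, 4, 0.5), ncol = 2),
                 matrix(runif(20 * 2, -6, 10), ncol = 2))
    for (eps in c(0.3, 0.8, 1.5)) {
      labs <- dbscan_cluster(pts, eps, 5)
      expect_true(check_dbscan_semantics(pts, eps, 5, labs),
                  label = sprintf("seed %d eps %.1f", s, eps))
    }
  }
})

test_that("DBSCAN limit cases behave", {
  same <- matrix(1, 30, 2)
  expect_equal(unique(dbscan_cluster(same, 0.1, 5)), 1L)
  set.seed(2)
  pts <- matrix(rnorm(100), 50, 2)
  expect_true(all(dbscan_cluster(pts, 1e-12, 5) == 0L))
  expect_error(dbscan_cluster(pts, 0, 5), "positive")
  expect_error(dbscan_cluster(pts, 1, 0), "min_pts")
})

test_that("cluster naming follows size and degenerate cases are flagged", {
  lp <- learning_params(matrix(rnorm(60, 50, 5), 10, 6))
  res <- split_learning_groups(c(rep(1L, 7), rep(2L, 2), 0L), lp)
  expect_equal(sum(res$labels$label == "learning"), 7L)
  expect_equal(sum(res$labels$label == "non_learning"), 2L)
  expect_equal(sum(res$labels$label == "noise"), 1L)
  expect_false(res$no_separation)
  res1 <- split_learning_groups(rep(1L, 10), lp)
  expect_true(res1$no_separation)
})

test_that("group comparisons report one-sample and Welch tests", {
  set.seed(9)
  tmat <- rbind(matrix(rnorm(300 * 6, 50, 3), 300, 6) +
                  outer(rep(2, 300), 0:5),          # learners rise
                matrix(rnorm(60 * 6, 52, 3), 60, 6))  # flat non-learners
  lp <- learning_params(tmat)
  labels <- c(rep("learning", 300), rep("non_learning", 60))
  gt <- group_tests(lp, labels)
  expect_setequal(unique(gt$test), c("one_sample_vs_zero", "welch_two_sample"))
  one <- gt[gt$test == "one_sample_vs_zero", ]
  expect_lt(abs(one$mean_non_learning), 1)
  w <- gt[gt$test == "welch_two_sample" & gt$metric == "avg_learning_rate", ]
  expect_lt(w$p, 1e-10)
  expect_gt(w$mean_learning, w$mean_non_learning)
})

test_that("a -0.11 SD shift at the screen's group size is detectable", {
  # the one-sample t-test must reject a mean of -0.11 SD with n = 1837
  # power at this effect and n is about 0.79 for the 1e-4 threshold
  set.seed(14)
  hits <- sapply(1:50, function(i) {
    x <- rnorm(1837, mean = -0.11, sd = 1)
    stats::t.test(x, mu = 0)$p.value < 1e-4
  })
  expect_gte(mean(hits), 0.7)
})

test_that("groups with zero variance yield NA p-values", {
  tmat <- rbind(matrix(rnorm(60, 50, 5), 10, 6),
                matrix(50, 5, 6))
  lp <- learning_params(tmat)
  labels <- c(rep("learning", 10), rep("non_learning", 5))
  gt <- group_tests(lp, labels)
  one <- gt[gt$test == "one_sample_vs_zero", ]
  expect_equal(one$mean_non_learning, 0)
  expect_true(is.na(one$p))
})

test_that("clustering pipeline is invariant to feature order and rescaling", {
  ds <- small_screen()
  sc <- score_screen(ds)
  lp <- learning_params(sc, smooth = TRUE)
  g3 <- ds$mice$mouse_id[ds$mice$generation == "G3"]
  lp <- lp[lp$mouse_id %in% g3, ]
  base <- cluster_learning(lp, min_pts = 5L)
  # permute feature columns
  feats <- rev(rotascreen:::learning_feature_names)
  perm <- cluster_learning(lp, min_pts = 5L, features = feats)
  expect_equal(sort(table(base$labels$label)), sort(table(perm$labels$label)))
  # uniformly rescale one feature; min-max absorbs the affine change
  lp2 <- lp
  lp2$avg_learning_rate <- lp2$avg_learning_rate * 37 + 5
  resc <- cluster_learning(lp2, min_pts = 5L)
  expect_equal(base$labels$label, resc$labels$label)
})
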