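# Neighbor lists within radius eps, computed in row chunks so memory stays
# bounded at chunk_size x n doubles.
radius_neighbors <- function(pts, eps, chunk_size = 512L) {
  n <- nrow(pts)
  sq <- rowSums(pts^2)
  out <- vector("list", n)
  eps2 <- eps^2
  for (from in seq(1L, n, by = chunk_size)) {
    to <- min(from + chunk_size - 1L, n)
    # squared distances chunk x n via the expansion |a-b|^2 = |a|^2+|b|^2-2ab
    d2 <- outer(sq[from:to], sq, "+") -
      2 * tcrossprod(pts[from:to, , drop = FALSE], pts)
    for (i in from:to)
      out[[i]] <- which(d2[i - from + 1L, ] <= eps2 + 1e-12)
  }
  out
}

#' Density-based clustering (DBSCAN)
#'
#' Standard DBSCAN semantics: a point with at least `min_pts` neighbors
#' within radius `eps` (itself included) is a core point; clusters are the
#' connected components of density-reachability grown from core points in
#' index order; non-core points within `eps` of a cluster's core point join
#' it as border points; everything else is labeled noise (0). Deterministic
#' for a fixed point order.
#'
#' @param pts numeric matrix, one row per point.
#' @param eps neighborhood radius (> 0).
#' @param min_pts minimum neighborhood size for a core point (>= 1).
#' @return integer vector of cluster labels, `0` = noise.
#' @export
dbscan_cluster <- function(pts, eps, min_pts = 10L) {
  pts <- as.matrix(pts)
  if (!is.numeric(eps) || length(eps) != 1L || eps <= 0)
    stop_format("eps must be a single positive number")
  if (min_pts < 1L) stop_format("min_pts must be >= 1")
  n <- nrow(pts)
  if (n == 0L) return(integer(0))
  nb <- radius_neighbors(pts, eps)
  core <- lengths(nb) >= min_pts
  labels <- integer(n)          # 0 = unassigned/noise
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    frontier <- nb[[i]]
    while (length(frontier)) {
      frontier <- frontier[labels[frontier] == 0L]
      if (!length(frontier)) break
      labels[frontier] <- cl
      frontier <- unique(unlist(nb[frontier[core[frontier]]]))
    }
  }
  labels
}

#' Choose eps from the k-distance curve
#'
#' Two stages. First the classic graphical rule: sort every point's
#' distance to its `min_pts`-th nearest neighbor and take the elbow of
#' that curve (the point farthest from the chord joining its endpoints).
#' The elbow alone tends to sit at the dense cluster's periphery and
#' leaves sparser clusters' borders as noise, so the radius is then grown
#' geometrically from the elbow and the largest value at which at least
#' two clusters remain (i.e. just before distinct density modes merge) is
#' returned; if no radius yields two clusters the bare elbow is kept.
#'
#' @param pts numeric matrix of points.
#' @param min_pts neighborhood size used for the k-distance and the merge
#'   scan.
#' @param grow multiplicative step of the expansion (default 1.15, 8
#'   steps); `grow = NULL` returns the bare elbow.
#' @return a single eps value.
#' @export
choose_eps <- function(pts, min_pts = 10L, grow = 1.15) {
  pts <- as.matrix(pts)
  n <- nrow(pts)
  if (n <= min_pts) stop_format("need more points than min_pts to choose eps")
  sq <- rowSums(pts^2)
  kd <- numeric(n)
  chunk <- 512L
  for (from in seq(1L, n, by = chunk)) {
    to <- min(from + chunk - 1L, n)
    d2 <- outer(sq[from:to], sq, "+") -
      2 * tcrossprod(pts[from:to, , drop = FALSE], pts)
    d2[d2 < 0] <- 0
    for (i in from:to)
      kd[i] <- sqrt(sort(d2[i - from + 1L, ], partial = min_pts + 1L)[min_pts + 1L])
  }
  y <- sort(kd)
  x <- seq_along(y)
  # distance from each curve point to the chord between its endpoints
  dx <- x[n] - x[1L]; dy <- y[n] - y[1L]
  dist <- abs(dy * (x - x[1L]) - dx * (y - y[1L])) / sqrt(dx^2 + dy^2)
  eps <- y[which.max(dist)]
  if (eps <= 0) eps <- max(y[y > 0][1L], 1e-8)
  if (is.null(grow)) return(eps)
  cand <- eps * grow^(0:8)
  n_clusters <- vapply(cand, function(e)
    length(setdiff(unique(dbscan_cluster(pts, e, min_pts)), 0L)), 1L)
  ok <- which(n_clusters >= 2L)
  if (length(ok)) cand[max(ok)] else eps
}

#' Cluster mice into learning and non-learning groups
#'
#' The clustering pipeline: min-max normalize the learning-curve features,
#' project onto the first `n_components` principal components, run DBSCAN
#' there, and name the larger of the two main clusters the learning group
#' and the smaller the non-learning group. Points DBSCAN leaves unassigned
#' are reported as noise and belong to neither group; if fewer than two
#' clusters emerge the result is flagged `no_separation`.
#'
#' @param lp a [learning_params()] data.frame.
#' @param eps DBSCAN radius, or `"auto"` for the k-distance elbow.
#' @param min_pts DBSCAN core-point threshold (default 10).
#' @param n_components principal components clustered on (default 2).
#' @param features feature columns used (defaults to the full set).
#' @return a `cluster_result`: list with `labels` (data.frame `mouse_id`,
#'   `pc1`, `pc2`, `cluster`, `label`), `explained_variance`, `eps`,
#'   `min_pts`, `no_separation`, and `summary` (per-group means).
#' @export
cluster_learning <- function(lp, eps = "auto", min_pts = 10L,
                             n_components = 2L,
                             features = learning_feature_names) {
  stopifnot(inherits(lp, "data.frame"), all(features %in% names(lp)))
  m <- minmax_normalize(lp[, features, drop = FALSE])
  p <- pca_features(m, n_components)
  pts <- p$scores
  if (identical(eps, "auto")) eps <- choose_eps(pts, min_pts)
  cl <- dbscan_cluster(pts, eps, min_pts)
  res <- split_learning_groups(cl, lp, pts)
  res$explained_variance <- p$explained_variance
  res$eps <- eps
  res$min_pts <- min_pts
  class(res) <- "cluster_result"
  res
}

#' Name clusters as learning / non-learning groups
#'
#' Maps raw cluster ids to group names: the most populous cluster is the
#' learning group, the second the non-learning group; any further clusters
#' and DBSCAN noise are labeled `"noise"`. With fewer than two clusters the
#' result is flagged as no separation and every clustered mouse falls in
#' the learning group.
#'
#' @param clusters integer vector of DBSCAN labels (0 = noise).
#' @param lp the matching [learning_params()] rows.
#' @param pts optional matrix of the clustered coordinates (for the label
#'   table's `pc1`/`pc2`).
#' @return list with `labels`, `no_separation`, `summary`.
#' @export
split_learning_groups <- function(clusters, lp, pts = NULL) {
  stopifnot(length(clusters) == nrow(lp))
  tab <- sort(table(clusters[clusters != 0L]), decreasing = TRUE)
  label <- rep("noise", length(clusters))
  no_sep <- length(tab) < 2L
  if (length(tab) >= 1L)
    label[clusters == as.integer(names(tab)[1L])] <- "learning"
  if (!no_sep)
    label[clusters == as.integer(names(tab)[2L])] <- "non_learning"
  labels <- data.frame(
    mouse_id = lp$mouse_id,
    pc1 = if (!is.null(pts)) pts[, 1L] else NA_real_,
    pc2 = if (!is.null(pts) && ncol(pts) >= 2L) pts[, 2L] else NA_real_,
    cluster = clusters, label = label, stringsAsFactors = FALSE)
  summ <- do.call(rbind, lapply(split(lp, label), function(g)
    data.frame(n = nrow(g),
               mean_learning_rate = mean(g$avg_learning_rate),
               mean_initial = mean(g$initial_performance),
               mean_final = mean(g$final_performance),
               mean_avg_performance = mean(g$avg_performance))))
  list(labels = labels, no_separation = no_sep, summary = summ)
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("<cluster_result>")
  if (x$no_separation) cat("  [no separation]")
  cat(sprintf("\n  eps = %.4g, min_pts = %d; PC1/PC2 explain %.1f%% of variance\n",
              x$eps, x$min_pts,
              100 * sum(x$explained_variance[1:2]) / sum(x$explained_variance)))
  print(x$summary)
  invisible(x)
}

#' Statistical comparison of learning groups
#'
#' One-sample t-test of the non-learning group's average learning rate
#' against zero, and Welch two-sample tests between the learning and
#' non-learning groups for average learning rate, initial, final and
#' average performance. Tests run on unsmoothed T-score features. Groups
#' with zero variance yield `NA` p-values.
#'
#' @param lp a [learning_params()] data.frame.
#' @param labels group label per row of `lp` (from `cluster_result$labels`
#'   or any character vector with `"learning"`/`"non_learning"`).
#' @return a `group_tests` data.frame: test, metric, group means, t, df, p.
#' @export
group_tests <- function(lp, labels) {
  if (is.data.frame(labels))
    labels <- labels$label[match(lp$mouse_id, labels$mouse_id)]
  stopifnot(length(labels) == nrow(lp))
  learn <- lp[labels == "learning", , drop = FALSE]
  non <- lp[labels == "non_learning", , drop = FALSE]
  if (nrow(non) < 2L || nrow(learn) < 2L)
    stop_format("both groups need at least 2 mice")
  safe_t <- function(x, y = NULL, mu = 0) {
    res <- tryCatch(
      if (is.null(y)) stats::t.test(x, mu = mu)
      else stats::t.test(x, y), error = function(e) NULL)
    if (is.null(res)) list(statistic = NA_real_, parameter = NA_real_,
                           p.value = NA_real_)
    else res
  }
  metrics <- c(avg_learning_rate = "avg_learning_rate",
               initial_performance = "initial_performance",
               final_performance = "final_performance",
               avg_performance = "avg_performance")
  one <- safe_t(non$avg_learning_rate, mu = 0)
  rows <- list(data.frame(
    test = "one_sample_vs_zero", metric = "avg_learning_rate",
    mean_learning = NA_real_, mean_non_learning = mean(non$avg_learning_rate),
    t = unname(one$statistic), df = unname(one$parameter),
    p = one$p.value, stringsAsFactors = FALSE))
  for (mm in metrics) {
    w <- safe_t(learn[[mm]], non[[mm]])
    rows[[length(rows) + 1L]] <- data.frame(
      test = "welch_two_sample", metric = mm,
      mean_learning = mean(learn[[mm]]),
      mean_non_learning = mean(non[[mm]]),
      t = unname(w$statistic), df = unname(w$parameter), p = w$p.value,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("group_tests", "data.frame")
  out
}
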