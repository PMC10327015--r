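#' Per-mouse learning-curve features
#'
#' Extracts the behavioral feature vector used for clustering from a
#' [score_screen()] result: the six trial T-scores `t1..t6`, the five
#' successive differences `d1..d5`, the average learning rate (mean of the
#' differences, which telescopes to `(t6 - t1)/5`), initial performance
#' (mean of trials 1--2), final performance (trial 6), early rise
#' (`t3 - t1`), late rise (`t6 - t4`) and average performance (mean of all
#' six T-scores).
#'
#' @param scores a `score_matrix`, or a numeric matrix/data.frame of six
#'   T-score columns with mouse ids as row names.
#' @param smooth apply [median_smooth()] to the curves before
#'   featurization? Default `FALSE`; group statistics must always be
#'   computed from unsmoothed scores.
#' @return a `learning_params` data.frame, one row per mouse. Mice with
#'   missing or non-finite trials are excluded with a message.
#' @export
learning_params <- function(scores, smooth = FALSE) {
  if (inherits(scores, "score_matrix")) {
    ids <- sort(unique(scores$mouse_id))
    tmat <- matrix(NA_real_, length(ids), 6L,
                   dimnames = list(ids, paste0("t", 1:6)))
    tmat[cbind(match(scores$mouse_id, ids), scores$trial)] <- scores$t
  } else {
    tmat <- as.matrix(scores)
    if (ncol(tmat) != 6L) stop_format("expected 6 T-score columns")
    if (is.null(rownames(tmat))) rownames(tmat) <- seq_len(nrow(tmat))
    colnames(tmat) <- paste0("t", 1:6)
  }
  ok <- rowSums(!is.finite(tmat)) == 0L
  if (any(!ok)) {
    log_msg("excluding %d mice with incomplete trial series", sum(!ok))
    tmat <- tmat[ok, , drop = FALSE]
  }
  if (smooth) {
    dn <- dimnames(tmat)
    tmat <- median_smooth(tmat)
    dimnames(tmat) <- dn
  }
  d <- tmat[, 2:6, drop = FALSE] - tmat[, 1:5, drop = FALSE]
  colnames(d) <- paste0("d", 1:5)
  out <- data.frame(
    mouse_id = rownames(tmat), tmat, d,
    avg_learning_rate = rowMeans(d),
    initial_performance = rowMeans(tmat[, 1:2, drop = FALSE]),
    final_performance = tmat[, 6L],
    early_rise = tmat[, 3L] - tmat[, 1L],
    late_rise = tmat[, 6L] - tmat[, 4L],
    avg_performance = rowMeans(tmat),
    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("learning_params", "data.frame")
  out
}

learning_feature_names <- c(paste0("t", 1:6), paste0("d", 1:5),
                            "avg_learning_rate", "initial_performance",
                            "final_performance", "early_rise", "late_rise",
                            "avg_performance")

#' Min-max normalization to [0, 1]
#'
#' Rescales each feature column to span exactly [0, 1], so that parameters
#' of different magnitudes contribute comparably to PCA. Constant columns
#' carry no information at this scale and are dropped with a warning.
#'
#' @param m numeric matrix or data.frame of features.
#' @return numeric matrix with each remaining column spanning [0, 1].
#' @export
minmax_normalize <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) == 0L || ncol(m) == 0L) stop_format("empty feature matrix")
  rng <- apply(m, 2L, range)
  span <- rng[2L, ] - rng[1L, ]
  if (any(span == 0)) {
    warning(sprintf("dropping constant feature column(s): %s",
                    paste(colnames(m)[span == 0], collapse = ", ")),
            call. = FALSE)
    m <- m[, span > 0, drop = FALSE]
    rng <- rng[, span > 0, drop = FALSE]
    span <- span[span > 0]
    if (ncol(m) == 0L) stop_format("all feature columns are constant")
  }
  sweep(sweep(m, 2L, rng[1L, ]), 2L, span, "/")
}

#' Principal component analysis of a feature matrix
#'
#' Thin wrapper around [stats::prcomp()] (covariance PCA of the centered
#' input; features are expected to be min-max scaled already).
#'
#' @param m numeric matrix (rows = mice, columns = features).
#' @param n_components number of components to retain in `scores`.
#' @return list with `scores` (n x n_components), `loadings` (orthonormal
#'   columns), `explained_variance` (all components, non-increasing) and
#'   `center`.
#' @export
pca_features <- function(m, n_components = 2L) {
  m <- as.matrix(m)
  if (nrow(m) < 2L) stop_format("PCA needs at least 2 rows")
  if (all(apply(m, 2L, stats::var) == 0)) stop_format("rank-0 input")
  p <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(p$x))
  list(scores = p$x[, seq_len(k), drop = FALSE],
       loadings = p$rotation,
       explained_variance = p$sdev^2,
       center = p$center)
}
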