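# squared Euclidean distances between rows of X (m x p) and C (k x p)
dist2_to_centers <- function(X, C) {
  D <- outer(rowSums(X^2), rowSums(C^2), "+") - 2 * X %*% t(C)
  D[D < 0] <- 0
  D
}

#' k-means clustering of slope profiles
#'
#' Lloyd's algorithm with squared Euclidean distance on raw
#' (unstandardized) slope profiles, restarted from `restarts` random
#' initializations (centers seeded at distinct data rows); the restart
#' with the smallest within-cluster sum of squares is returned. If a
#' cluster empties during iteration, its centroid is re-seeded at the
#' point farthest from its assigned centroid. After each restart's batch
#' phase converges, an online phase applies single-point reassignments
#' using the exact objective change (including the centroid shift) until
#' no move improves — the batch/online scheme standard k-means
#' implementations use, which escapes batch-phase local optima.
#' Deterministic given `seed`.
#'
#' @param beta A `beta_matrix` or a plain numeric matrix (rows =
#'   observations).
#' @param k Number of clusters (>= 2, <= rows).
#' @param restarts Number of random restarts (default 10).
#' @param seed Integer seed.
#' @param max_iter Maximum Lloyd iterations per restart.
#' @param standardize Z-score columns before clustering (default FALSE;
#'   sensitivity option).
#' @return Object of class `cluster_solution`: `k`, `labels` (1..k per
#'   row), `centroids` (k x bins, means of member rows), `withinss`
#'   (per-cluster), `tot_withinss`, `restarts`, `seed`.
#' @export
kmeans_cluster <- function(beta, k, restarts = 10L, seed = 1L,
                           max_iter = 100L, standardize = FALSE) {
  X <- if (inherits(beta, "beta_matrix")) beta$beta else as.matrix(beta)
  m <- nrow(X)
  k <- as.integer(k)
  if (k < 2L) stop("`k` must be at least 2")
  if (k > m) stop("`k` (", k, ") exceeds the number of rows (", m, ")")
  if (standardize) X <- scale(X)

  set.seed(as.integer(seed))
  best <- NULL
  for (r in seq_len(restarts)) {
    C <- X[sample.int(m, k), , drop = FALSE]
    lab <- integer(m)
    for (it in seq_len(max_iter)) {
      D <- dist2_to_centers(X, C)
      new_lab <- max.col(-D, ties.method = "first")
      # re-seed any empty cluster at the point farthest from its centroid
      repeat {
        empty <- setdiff(seq_len(k), unique(new_lab))
        if (!length(empty)) break
        dmin <- D[cbind(seq_len(m), new_lab)]
        far <- which.max(dmin)
        C[empty[1L], ] <- X[far, ]
        D <- dist2_to_centers(X, C)
        new_lab <- max.col(-D, ties.method = "first")
      }
      if (identical(new_lab, lab)) break
      lab <- new_lab
      C <- rowsum(X, lab) / as.vector(table(factor(lab, seq_len(k))))
    }
    lab <- online_phase(X, lab, k)
    C <- rowsum(X, lab) / as.vector(table(factor(lab, seq_len(k))))
    wss <- rowsum(rowSums((X - C[lab, , drop = FALSE])^2), lab)
    tot <- sum(wss)
    if (is.null(best) || tot < best$tot_withinss) {
      best <- list(k = k, labels = lab, centroids = C,
                   withinss = as.vector(wss), tot_withinss = tot)
    }
  }
  best$restarts <- as.integer(restarts)
  best$seed <- as.integer(seed)
  best$standardized <- standardize
  class(best) <- "cluster_solution"
  best
}

# Online refinement: steepest-descent single-point reassignments with the
# exact WSS change (n/(n-1) removal, n/(n+1) insertion factors); stops
# when no move improves. Each move strictly decreases the objective.
online_phase <- function(X, lab, k, max_moves = 100L * k) {
  m <- nrow(X)
  for (mv in seq_len(max_moves)) {
    n <- tabulate(lab, k)
    C <- rowsum(X, lab) / n
    D <- dist2_to_centers(X, C)
    removal <- D[cbind(seq_len(m), lab)] * n[lab] / (n[lab] - 1)
    removal[n[lab] == 1L] <- -Inf  # never empty a cluster
    insertion <- sweep(D, 2L, n / (n + 1), "*")
    insertion[cbind(seq_len(m), lab)] <- Inf
    delta <- insertion - removal
    best <- which.min(delta)
    if (delta[best] >= -1e-12) break
    i <- (best - 1L) %% m + 1L
    lab[i] <- (best - 1L) %/% m + 1L
  }
  lab
}

#' Mean silhouette value of a clustering
#'
#' Rousseeuw's silhouette with Euclidean distance (the metric consistent
#' with squared-Euclidean k-means); singleton clusters score 0.
#'
#' @param labels Integer cluster labels.
#' @param d A `dist` object over the same rows (or a matrix to compute
#'   distances from).
#' @return Mean silhouette width in `[-1, 1]`.
#' @export
mean_silhouette <- function(labels, d) {
  if (!inherits(d, "dist")) d <- dist(d)
  sil <- cluster::silhouette(labels, d)
  mean(sil[, "sil_width"])
}

#' Silhouette scan over candidate cluster counts
#'
#' Runs [kmeans_cluster()] for each k in `k_range` and scores the
#' solution by mean silhouette; the best k attains the maximum, with ties
#' broken toward the smallest k. Rows may optionally be subsampled for
#' the silhouette computation (the clustering itself always uses all
#' rows).
#'
#' @inheritParams kmeans_cluster
#' @param k_range Candidate cluster counts (default 2:10).
#' @param subsample Number of rows to subsample for silhouette scoring;
#'   0 (default) uses all rows.
#' @return Object of class `silhouette_scan`: `k`, `silhouette` (mean
#'   value per k), `best_k`, and `solutions` (the fitted
#'   `cluster_solution` per k, named by k).
#' @export
silhouette_scan <- function(beta, k_range = 2:10, restarts = 10L,
                            seed = 1L, subsample = 0L) {
  X <- if (inherits(beta, "beta_matrix")) beta$beta else as.matrix(beta)
  m <- nrow(X)
  if (m <= max(k_range)) stop("need more rows than the largest k")
  if (all(apply(X, 2L, function(col) length(unique(col)) == 1L)))
    stop("all rows are identical; silhouette is undefined")
  set.seed(as.integer(seed))
  idx <- if (subsample > 0L && subsample < m)
    sort(sample.int(m, subsample)) else seq_len(m)
  d <- dist(X[idx, , drop = FALSE])
  msil <- numeric(length(k_range))
  sols <- vector("list", length(k_range))
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    sols[[i]] <- kmeans_cluster(X, k, restarts = restarts,
                                seed = as.integer(seed) + k)
    msil[i] <- mean_silhouette(sols[[i]]$labels[idx], d)
  }
  names(sols) <- as.character(k_range)
  structure(list(k = k_range, silhouette = msil,
                 best_k = k_range[which.max(msil)],
                 solutions = sols),
            class = "silhouette_scan")
}
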