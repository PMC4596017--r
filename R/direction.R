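# stack the three eigenvalue lattices into a voxels x 3 matrix for
# the voxels selected by `idx`
eigen_rows <- function(eig, idx) {
  cbind(x = eig$x[idx], y = eig$y[idx], z = eig$z[idx])
}

#' Dominant-direction profile of labeled clusters
#'
#' For each cluster, retains the voxels whose largest principal-direction
#' eigenvalue is at least `threshold` (inclusive), assigns each retained
#' voxel to its argmax direction (ties broken in the fixed order x, y, z
#' and tallied), and reports per-direction counts and proportions. A
#' cluster with no retained voxel gets NA proportions and an `undefined`
#' flag (with a warning), never silent zeros.
#'
#' @param labels Integer label lattice (0 = background).
#' @param eig An `eigenvalue_maps` object (or list with arrays `x`, `y`,
#'   `z`).
#' @param threshold Retention threshold in (0, 1) (default 0.4).
#' @return data.frame with one row per cluster: `cluster`, `n_voxels`,
#'   `n_retained`, `retained_fraction`, `count_x/y/z`, `prop_x/y/z`,
#'   `n_ties`, `undefined`; threshold attached as attribute.
#' @export
dominant_direction_profile <- function(labels, eig, threshold = 0.4) {
  stopifnot(threshold > 0, threshold < 1,
            identical(dim(labels), dim(eig$x)),
            identical(dim(eig$x), dim(eig$y)),
            identical(dim(eig$x), dim(eig$z)))
  K <- max(labels)
  out <- vector("list", K)
  for (c in seq_len(K)) {
    idx <- which(labels == c)
    E <- eigen_rows(eig, idx)
    mx <- do.call(pmax, as.data.frame(E))
    keep <- mx >= threshold
    n_ret <- sum(keep)
    if (n_ret == 0L) {
      warning("cluster ", c, ": no voxel reaches eigenvalue threshold ",
              threshold, "; direction profile undefined")
      counts <- rep(NA_integer_, 3L); props <- rep(NA_real_, 3L)
      ties <- NA_integer_
    } else {
      Ek <- E[keep, , drop = FALSE]
      dom <- max.col(Ek, ties.method = "first")   # tie order x -> y -> z
      ties <- sum(rowSums(Ek == mx[keep]) > 1L)
      counts <- tabulate(dom, nbins = 3L)
      props <- counts / n_ret
    }
    out[[c]] <- data.frame(cluster = c, n_voxels = length(idx),
                           n_retained = n_ret,
                           retained_fraction = n_ret / length(idx),
                           count_x = counts[1], count_y = counts[2],
                           count_z = counts[3],
                           prop_x = props[1], prop_y = props[2],
                           prop_z = props[3],
                           n_ties = ties,
                           undefined = n_ret == 0L)
  }
  structure(do.call(rbind, out), threshold = threshold)
}

#' Sorted eigenvalue matrix for one cluster
#'
#' Retained voxels of one cluster, grouped by dominant direction in the
#' order x, y, z, sorted by descending maximum eigenvalue within each
#' group, with the linear voxel coordinate as a final deterministic
#' tie-break.
#'
#' @inheritParams dominant_direction_profile
#' @param cluster Cluster label to extract.
#' @return List with `values` (retained voxels x 3 matrix, columns x, y,
#'   z), `direction` (dominant direction per row), `voxel_index` (linear
#'   lattice indices), `threshold`.
#' @export
sorted_eigen_matrix <- function(labels, eig, threshold = 0.4, cluster = 1L) {
  stopifnot(threshold > 0, threshold < 1)
  idx <- which(labels == cluster)
  E <- eigen_rows(eig, idx)
  mx <- do.call(pmax, as.data.frame(E))
  keep <- mx >= threshold
  E <- E[keep, , drop = FALSE]
  idx <- idx[keep]
  mx <- mx[keep]
  dom <- if (nrow(E)) max.col(E, ties.method = "first") else integer(0)
  ord <- order(dom, -mx, idx)
  list(values = E[ord, , drop = FALSE],
       direction = DIRECTIONS[dom[ord]],
       voxel_index = idx[ord],
       threshold = threshold)
}
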