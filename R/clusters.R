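#' Per-cluster, per-bin slope summary
#'
#' Mean and standard deviation of the member slope profiles in each
#' cluster and age bin, with voxel counts. Means equal the solution's
#' centroids by construction.
#'
#' @param sol A `cluster_solution`.
#' @param beta The `beta_matrix` (or matrix) the solution was fitted on.
#' @return data.frame with columns `cluster`, `bin`, `n_voxels`,
#'   `mean_slope`, `sd_slope`.
#' @export
cluster_slope_summary <- function(sol, beta) {
  X <- if (inherits(beta, "beta_matrix")) beta$beta else as.matrix(beta)
  stopifnot(length(sol$labels) == nrow(X))
  out <- list()
  for (c in seq_len(sol$k)) {
    rows <- X[sol$labels == c, , drop = FALSE]
    sds <- apply(rows, 2L, sd)
    sds[is.na(sds)] <- 0   # one-member cluster
    out[[c]] <- data.frame(cluster = c, bin = seq_len(ncol(X)),
                           n_voxels = nrow(rows),
                           mean_slope = colMeans(rows),
                           sd_slope = sds, row.names = NULL)
  }
  do.call(rbind, out)
}

#' Piecewise-linear volume trajectory from per-bin mean slopes
#'
#' Reconstructs a continuous trajectory whose gradient on each age bin
#' equals the cluster's mean slope there, anchored at a given value at
#' the first bin edge.
#'
#' @param slopes Mean slope per bin (tissue amount per year).
#' @param bin_edges Bin edges (length = bins + 1).
#' @param anchor Trajectory value at the first edge (> 0).
#' @return Object of class `trajectory_curve`: `knot_ages`,
#'   `knot_values`, `slopes`, `anchor`.
#' @export
trajectory_from_slopes <- function(slopes,
                                   bin_edges = c(4, 8, 10.5, 13.5, 18.5),
                                   anchor = 1) {
  stopifnot(length(bin_edges) == length(slopes) + 1L, anchor > 0)
  values <- anchor + cumsum(c(0, slopes * diff(bin_edges)))
  structure(list(knot_ages = bin_edges, knot_values = values,
                 slopes = slopes, anchor = anchor),
            class = "trajectory_curve")
}

#' Evaluate a trajectory curve at arbitrary ages
#'
#' @param traj A `trajectory_curve`.
#' @param age Ages within the knot range.
#' @return Trajectory values (exact piecewise-linear interpolation).
#' @export
trajectory_value <- function(traj, age) {
  stopifnot(all(age >= traj$knot_ages[1]),
            all(age <= traj$knot_ages[length(traj$knot_ages)]))
  stats::approx(traj$knot_ages, traj$knot_values, xout = age)$y
}
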