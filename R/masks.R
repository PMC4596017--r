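#' Build disjoint explicit tissue masks
#'
#' A voxel enters the gray mask iff its mean gray value exceeds the
#' threshold AND exceeds the mean white value; symmetrically for white.
#' The strict inequality against the other tissue guarantees the two
#' masks never overlap; exact ties belong to neither mask.
#'
#' @param gm_mean,wm_mean Co-registered 3D arrays of mean tissue values
#'   (mean probability or normalized mean amount).
#' @param threshold Inclusion threshold in (0, 1) (default 0.4).
#' @return List with logical arrays `gm` and `wm`; the threshold is
#'   attached as attribute `threshold`.
#' @export
build_masks <- function(gm_mean, wm_mean, threshold = 0.4) {
  stopifnot(identical(dim(gm_mean), dim(wm_mean)),
            threshold > 0, threshold < 1)
  gm <- gm_mean > threshold & gm_mean > wm_mean
  wm <- wm_mean > threshold & wm_mean > gm_mean
  if (!any(gm)) stop("gray matter mask is empty at threshold ", threshold)
  if (!any(wm)) stop("white matter mask is empty at threshold ", threshold)
  structure(list(gm = gm, wm = wm), threshold = threshold)
}

#' Mean map over subjects
#'
#' @param maps Subject-by-voxel matrix (or list of 3D arrays).
#' @param grid Grid shape of the lattice.
#' @return 3D array of voxelwise means.
#' @export
mean_map <- function(maps, grid) {
  maps <- as_map_matrix(maps)
  array(colMeans(maps), grid)
}

# normalize map input to a subjects x voxels matrix
as_map_matrix <- function(maps) {
  if (is.matrix(maps)) return(maps)
  if (is.list(maps)) return(do.call(rbind, lapply(maps, as.vector)))
  stop("`maps` must be a subjects x voxels matrix or a list of arrays")
}

#' Total tissue amount of one map
#'
#' Sum of masked voxel values times the voxel volume.
#'
#' @param map 3D array or flattened numeric vector.
#' @param mask Logical array/vector of the same lattice.
#' @param voxel_size Isotropic voxel size in mm (default 1).
#' @return Scalar tissue amount (units: value units times mm^3).
#' @export
total_volume <- function(map, mask, voxel_size = 1) {
  sum(as.vector(map)[as.vector(mask)]) * voxel_size^3
}

#' Squared-distance outlier screen within one age bin
#'
#' For each subject, the squared Euclidean distance of the masked map to
#' the bin's voxelwise sample mean; subjects are flagged when their
#' distance exceeds `median + mad_mult * MAD` of the bin distances.
#'
#' @param maps Subject-by-voxel matrix (or list of 3D arrays) for the
#'   subjects of one bin.
#' @param mask Logical array/vector.
#' @param mad_mult Robust cutoff multiplier (default 3).
#' @return data.frame with `subject_id` (rownames of `maps` if present),
#'   `distance`, and `flagged`; the cutoff is attribute `cutoff`.
#' @export
detect_outliers <- function(maps, mask, mad_mult = 3) {
  maps <- as_map_matrix(maps)
  if (nrow(maps) < 3L) stop("need at least 3 subjects in the bin")
  Y <- maps[, as.vector(mask), drop = FALSE]
  ctr <- colMeans(Y)
  d <- rowSums(sweep(Y, 2L, ctr)^2)
  cutoff <- median(d) + mad_mult * mad(d)
  ids <- rownames(maps)
  if (is.null(ids)) ids <- sprintf("s%03d", seq_len(nrow(maps)))
  structure(data.frame(subject_id = ids, distance = d,
                       flagged = d > cutoff, row.names = NULL,
                       stringsAsFactors = FALSE),
            cutoff = cutoff)
}

# embed masked values into a lattice
embed_in_lattice <- function(values, mask, fill = NA_real_) {
  arr <- array(fill, dim(mask))
  arr[mask] <- values
  arr
}
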