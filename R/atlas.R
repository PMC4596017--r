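#' Generate a ground-truth region atlas
#'
#' Lays out `k_gm` gray-matter and `k_wm` white-matter regions as connected
#' rectangular blocks on a 3D grid, with disjoint supports. Regions are
#' packed into non-touching lattice cells; within each cell a gray and a
#' white block are stacked along z and share a face, so every white region
#' is adjacent to exactly one designated gray region (the generative
#' pairing). Each region carries a 4-vector of per-bin age slopes; slope
#' profiles of distinct regions within a tissue are rejection-sampled to a
#' minimum Euclidean separation so that clustering on recovered slopes is
#' well posed. Each white region is assigned a dominant principal
#' direction, cycling x, y, z.
#'
#' @param grid Grid shape, 3 positive integers (default `c(32,32,32)`).
#' @param k_gm,k_wm Number of gray / white regions (>= 2).
#' @param seed Integer seed.
#' @param voxel_size Isotropic voxel size in mm (default 4).
#' @param n_bins Number of age bins the slope table covers (default 4).
#' @param baseline_gm,baseline_wm Region baseline tissue amount.
#' @param slope_range_gm,slope_range_wm Uniform ranges (tissue amount per
#'   year) the per-bin slopes are drawn from.
#' @param min_slope_sep Minimum Euclidean distance between the slope
#'   profiles of distinct regions of one tissue.
#' @param slope_jitter_sd Standard deviation of the per-voxel slope
#'   heterogeneity within a region (tissue amount per year). The true
#'   slope at a voxel is its region's bin profile plus a fixed Gaussian
#'   deviation — a property of the synthetic brain, identical for all
#'   subjects — mirroring the within-cluster slope spread of real data.
#' @return An object of class `ground_truth_atlas`: a list with integer
#'   label arrays `gm_labels` / `wm_labels` (0 = background), slope
#'   matrices `slopes$gm` / `slopes$wm` (region x bin), per-voxel true
#'   slope lattices `slope_fields$gm` / `$wm` (one array per bin),
#'   `wm_direction` (one of `"x"`, `"y"`, `"z"` per white region),
#'   `wm_partner_gm` (the gray region each white region touches, NA if
#'   none), baselines, grid and voxel size.
#' @export
generate_atlas <- function(grid = c(32L, 32L, 32L),
                           k_gm = 4L, k_wm = 4L,
                           seed = 7L,
                           voxel_size = 4,
                           n_bins = 4L,
                           baseline_gm = 0.7, baseline_wm = 0.7,
                           slope_range_gm = c(-0.04, 0.01),
                           slope_range_wm = c(-0.01, 0.04),
                           min_slope_sep = 0.04,
                           slope_jitter_sd = 0.0075) {
  grid <- as.integer(grid)
  stopifnot(length(grid) == 3L, all(grid >= 1L))
  k_gm <- as.integer(k_gm); k_wm <- as.integer(k_wm)
  if (k_gm < 2L || k_wm < 2L) stop("`k_gm` and `k_wm` must be >= 2")

  n_cells <- max(k_gm, k_wm)
  cell_dims <- cell_lattice_dims(n_cells)
  cell_size <- grid %/% cell_dims
  usable <- cell_size - 2L   # 1-voxel margin per side keeps cells apart
  n_paired <- min(k_gm, k_wm)
  # a paired cell stacks two blocks (>= 3 voxels each) along z
  if (any(usable[1:2] < 3L) || usable[3] < 6L)
    stop("cannot pack ", k_gm, " + ", k_wm, " regions into a ",
         paste(grid, collapse = "x"), " grid: lattice cells too small")

  set.seed(as.integer(seed))

  gm_labels <- array(0L, grid)
  wm_labels <- array(0L, grid)
  wm_partner_gm <- rep(NA_integer_, k_wm)

  cells <- as.matrix(expand.grid(x = seq_len(cell_dims[1]),
                                 y = seq_len(cell_dims[2]),
                                 z = seq_len(cell_dims[3])))
  place_block <- function(labels, region, x0, bx, y0, by, z0, bz) {
    labels[x0:(x0 + bx - 1L), y0:(y0 + by - 1L), z0:(z0 + bz - 1L)] <-
      as.integer(region)
    labels
  }

  # block extents are drawn from a balanced band (60-80% of the usable
  # cell extent; 40-48% along z for stacked pairs) so regions of one
  # tissue have comparable volumes, as covariance clusters do
  rint <- function(lo, hi) {
    lo <- as.integer(lo); hi <- max(lo, as.integer(hi))
    if (lo == hi) lo else sample(lo:hi, 1L)
  }
  gm_next <- 1L; wm_next <- 1L
  for (i in seq_len(n_cells)) {
    orig <- (cells[i, ] - 1L) * cell_size + 2L   # first usable voxel
    # common x/y footprint (guarantees a shared face for paired blocks)
    bx <- rint(max(3, round(0.6 * usable[1])), round(0.8 * usable[1]))
    by <- rint(max(3, round(0.6 * usable[2])), round(0.8 * usable[2]))
    x0 <- orig[1] + sample.int(usable[1] - bx + 1L, 1L) - 1L
    y0 <- orig[2] + sample.int(usable[2] - by + 1L, 1L) - 1L
    if (i <= n_paired) {
      bz_gm <- rint(max(3, round(0.4 * usable[3])),
                    round(0.48 * usable[3]))
      bz_wm <- rint(max(3, round(0.4 * usable[3])),
                    round(0.48 * usable[3]))
      z0 <- orig[3] + sample.int(usable[3] - bz_gm - bz_wm + 1L, 1L) - 1L
      gm_labels <- place_block(gm_labels, gm_next, x0, bx, y0, by, z0, bz_gm)
      wm_labels <- place_block(wm_labels, wm_next, x0, bx, y0, by,
                               z0 + bz_gm, bz_wm)
      wm_partner_gm[wm_next] <- gm_next
      gm_next <- gm_next + 1L; wm_next <- wm_next + 1L
    } else if (gm_next <= k_gm) {
      bz <- rint(max(3, round(0.6 * usable[3])), round(0.8 * usable[3]))
      z0 <- orig[3] + sample.int(usable[3] - bz + 1L, 1L) - 1L
      gm_labels <- place_block(gm_labels, gm_next, x0, bx, y0, by, z0, bz)
      gm_next <- gm_next + 1L
    } else {
      bz <- rint(max(3, round(0.6 * usable[3])), round(0.8 * usable[3]))
      z0 <- orig[3] + sample.int(usable[3] - bz + 1L, 1L) - 1L
      wm_labels <- place_block(wm_labels, wm_next, x0, bx, y0, by, z0, bz)
      wm_next <- wm_next + 1L
    }
  }

  slopes_gm <- draw_separated_profiles(k_gm, n_bins, slope_range_gm,
                                       min_slope_sep)
  slopes_wm <- draw_separated_profiles(k_wm, n_bins, slope_range_wm,
                                       min_slope_sep)
  wm_direction <- DIRECTIONS[(seq_len(k_wm) - 1L) %% 3L + 1L]

  slope_field <- function(labels, slopes) {
    fields <- vector("list", n_bins)
    in_tissue <- labels > 0L
    for (b in seq_len(n_bins)) {
      f <- array(0, grid)
      f[in_tissue] <- slopes[cbind(labels[in_tissue], b)] +
        rnorm(sum(in_tissue), 0, slope_jitter_sd)
      fields[[b]] <- f
    }
    fields
  }
  fields_gm <- slope_field(gm_labels, slopes_gm)
  fields_wm <- slope_field(wm_labels, slopes_wm)

  structure(list(grid = grid, voxel_size = voxel_size,
                 gm_labels = gm_labels, wm_labels = wm_labels,
                 slopes = list(gm = slopes_gm, wm = slopes_wm),
                 slope_fields = list(gm = fields_gm, wm = fields_wm),
                 wm_direction = wm_direction,
                 wm_partner_gm = wm_partner_gm,
                 baselines = c(gm = baseline_gm, wm = baseline_wm),
                 min_slope_sep = min_slope_sep),
            class = "ground_truth_atlas")
}

# near-cubic lattice dimensions holding at least n cells
cell_lattice_dims <- function(n) {
  nz <- max(1L, floor(n^(1 / 3)))
  ny <- max(1L, floor(sqrt(n / nz)))
  nx <- as.integer(ceiling(n / (ny * nz)))
  as.integer(c(nx, ny, nz))
}

# rejection-sample k profile vectors with pairwise separation >= min_sep
draw_separated_profiles <- function(k, n_bins, range, min_sep,
                                    max_tries = 10000L) {
  out <- matrix(NA_real_, k, n_bins)
  accepted <- 0L
  for (try in seq_len(max_tries)) {
    cand <- runif(n_bins, range[1], range[2])
    ok <- accepted == 0L ||
      all(sqrt(colSums((t(out[seq_len(accepted), , drop = FALSE]) - cand)^2))
          >= min_sep)
    if (ok) {
      accepted <- accepted + 1L
      out[accepted, ] <- cand
      if (accepted == k) return(out)
    }
  }
  stop("could not draw ", k, " slope profiles separated by ", min_sep,
       " within range [", range[1], ", ", range[2], "]")
}
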