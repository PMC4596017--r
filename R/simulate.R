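#' 3D Gaussian smoothing
#'
#' Separable Gaussian filter with kernel width given as full width at half
#' maximum in mm, converted to voxels via
#' `sigma = fwhm / (2 * sqrt(2 * log(2))) / voxel_size` and truncated at 4
#' sigma. Boundaries are zero-padded (values beyond the grid are treated
#' as 0), matching the convention of standard neuroimaging smoothers.
#'
#' @param vol 3D numeric array.
#' @param fwhm Kernel FWHM in mm; `0` returns the input unchanged.
#' @param voxel_size Isotropic voxel size in mm.
#' @return Smoothed array of the same shape.
#' @export
gaussian_smooth <- function(vol, fwhm, voxel_size = 1) {
  stopifnot(length(dim(vol)) == 3L, fwhm >= 0, voxel_size > 0)
  if (fwhm == 0) return(vol)
  sigma <- fwhm / (2 * sqrt(2 * log(2))) / voxel_size
  r <- max(1L, ceiling(4 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  for (axis in 1:3) {
    d <- dim(vol)[1]
    K <- matrix(0, d, d)
    for (off in (-r):r) {
      idx <- seq_len(d)
      keep <- idx + off >= 1L & idx + off <= d
      K[cbind(idx[keep], (idx + off)[keep])] <- k[off + r + 1L]
    }
    vol <- array(K %*% matrix(vol, d, length(vol) / d), dim(vol))
    vol <- aperm(vol, c(2, 3, 1))
  }
  vol
}

# zero-sum additive site offsets spanning +/- amplitude
site_offset_vector <- function(n_sites, amplitude) {
  if (n_sites == 1L) return(0)
  amplitude * seq(-1, 1, length.out = n_sites)
}

site_index <- function(site) as.integer(sub("^site", "", site))

bin_mid_ages <- function(bin_edges) {
  (bin_edges[-length(bin_edges)] + bin_edges[-1]) / 2
}

# Deterministic builder for one subject's pair of maps; assumes the RNG
# state is already positioned (callers seed it).
build_subject_maps <- function(record, atlas, effects, bin_edges, n_sites) {
  mids <- bin_mid_ages(bin_edges)
  dage <- record$age - mids[record$age_bin]
  site_off <- site_offset_vector(n_sites, effects$site_amplitude)[
    site_index(record$site)]
  out <- list()
  for (tissue in c("gm", "wm")) {
    labels <- if (tissue == "gm") atlas$gm_labels else atlas$wm_labels
    field <- atlas$slope_fields[[tissue]][[record$age_bin]]
    sensitive <- effects[[paste0("site_sensitive_", tissue)]]
    vol <- array(0, atlas$grid)
    in_tissue <- labels > 0L
    vol[in_tissue] <- atlas$baselines[[tissue]] +
      field[in_tissue] * dage +
      (record$gender == "M") * effects$gender_offset +
      effects$resolution_coef * record$resolution
    if (!is.null(sensitive) && length(sensitive))
      vol[labels %in% sensitive] <- vol[labels %in% sensitive] + site_off
    if (effects$noise_sd > 0)
      vol <- vol + array(rnorm(length(vol), 0, effects$noise_sd), atlas$grid)
    if (effects$fwhm > 0)
      vol <- gaussian_smooth(vol, effects$fwhm, atlas$voxel_size)
    vol[vol < 0] <- 0
    out[[tissue]] <- vol
  }
  out
}

#' Simulate one subject's modulated tissue-amount maps
#'
#' Generates a gray and a white matter map on the atlas grid. Inside each
#' region the voxel value is the region baseline plus the region's bin
#' slope times (age minus bin midpoint age), plus a gender offset, an
#' additive site offset (only in the configured site-sensitive regions),
#' and a linear resolution effect; i.i.d. Gaussian noise is added over the
#' whole grid, the map is smoothed with a Gaussian kernel (FWHM in mm) and
#' clipped at 0. Maps are generated already spatially normalized and
#' modulated; no registration is simulated.
#'
#' @param record One-row data.frame as produced by [generate_cohort()].
#' @param atlas A `ground_truth_atlas`.
#' @param effects List of effect parameters (see [default_config()]
#'   `$effects`): `gender_offset`, `site_amplitude`,
#'   `site_sensitive_gm`/`_wm`, `resolution_coef`, `noise_sd`, `fwhm`.
#' @param seed Integer seed.
#' @param bin_edges Age-bin edges (used for the bin midpoint ages).
#' @param n_sites Number of sites in the cohort design.
#' @return List with 3D arrays `gm` and `wm`.
#' @export
simulate_subject_maps <- function(record, atlas, effects = NULL, seed = 1L,
                                  bin_edges = c(4, 8, 10.5, 13.5, 18.5),
                                  n_sites = 6L) {
  effects <- resolve_effects(effects)
  if (effects$noise_sd < 0) stop("`noise_sd` must be nonnegative")
  set.seed(as.integer(seed))
  build_subject_maps(record, atlas, effects, bin_edges, n_sites)
}

resolve_effects <- function(effects) {
  defaults <- default_config()$effects
  if (is.null(effects)) return(defaults)
  defaults[names(effects)] <- effects
  defaults
}

#' Simulate maps for a whole cohort
#'
#' Convenience wrapper over the same generative model as
#' [simulate_subject_maps()], returning subject-by-voxel matrices (row
#' `s` is subject `s`'s flattened lattice in R's column-major voxel
#' order) for each tissue. Deterministic given `seed`.
#'
#' @inheritParams simulate_subject_maps
#' @param records Cohort data.frame.
#' @return List with matrices `gm` and `wm` (subjects x voxels), `grid`,
#'   and `voxel_size`.
#' @export
simulate_cohort_maps <- function(records, atlas, effects = NULL, seed = 1L,
                                 bin_edges = c(4, 8, 10.5, 13.5, 18.5),
                                 n_sites = 6L) {
  effects <- resolve_effects(effects)
  if (effects$noise_sd < 0) stop("`noise_sd` must be nonnegative")
  n <- nrow(records)
  V <- prod(atlas$grid)
  gm <- matrix(0, n, V); wm <- matrix(0, n, V)
  set.seed(as.integer(seed))
  for (s in seq_len(n)) {
    maps <- build_subject_maps(records[s, ], atlas, effects, bin_edges,
                               n_sites)
    gm[s, ] <- as.vector(maps$gm)
    wm[s, ] <- as.vector(maps$wm)
  }
  rownames(gm) <- rownames(wm) <- records$subject_id
  list(gm = gm, wm = wm, grid = atlas$grid, voxel_size = atlas$voxel_size)
}

#' Simulate principal-direction eigenvalue maps
#'
#' Three co-registered lattices of direction weights in `[0,1]`, one per
#' canonical axis (x right-left, y anterior-posterior, z
#' superior-inferior). Within each white-matter region the assigned
#' dominant direction is drawn near `dominance` and the other two near
#' `(1 - dominance) / 2`; all values get additive Gaussian noise and are
#' clipped to `[0,1]`. Background (including gray matter) is noise near 0.
#'
#' @param atlas A `ground_truth_atlas`.
#' @param dominance Dominant-direction weight in `(0, 1]`.
#' @param noise_sd Noise standard deviation (>= 0).
#' @param seed Integer seed.
#' @return Object of class `eigenvalue_maps`: list with arrays `x`, `y`,
#'   `z`, plus `grid` and `voxel_size`.
#' @export
simulate_eigenvalue_maps <- function(atlas, dominance = 0.8,
                                     noise_sd = 0.05, seed = 1L) {
  stopifnot(dominance > 0, dominance <= 1, noise_sd >= 0)
  set.seed(as.integer(seed))
  V <- prod(atlas$grid)
  minor <- (1 - dominance) / 2
  maps <- list()
  for (d in DIRECTIONS) {
    vals <- rnorm(V, 0, noise_sd)          # background near 0
    for (r in seq_len(nrow(atlas$slopes$wm))) {
      idx <- which(atlas$wm_labels == r)
      level <- if (atlas$wm_direction[r] == d) dominance else minor
      vals[idx] <- level + rnorm(length(idx), 0, noise_sd)
    }
    vals[vals < 0] <- 0
    vals[vals > 1] <- 1
    maps[[d]] <- array(vals, atlas$grid)
  }
  structure(c(maps, list(grid = atlas$grid, voxel_size = atlas$voxel_size)),
            class = "eigenvalue_maps")
}

#' Simulate per-lobe native-intensity tables
#'
#' Emulates mean gray and white matter image intensities extracted in each
#' subject's native space for four lobes. Gray intensity is the lobe base
#' plus noise; white intensity is `gm * (1 + C)` with a true contrast
#' `C = base_contrast + site offset + age_coef * age + noise`. Site
#' offsets are zero-sum across sites with a per-lobe amplitude.
#'
#' @param records Cohort data.frame.
#' @param base_gm Base gray intensity per lobe (length 4, canonical lobe
#'   order frontal, temporal, parietal, occipital; all > 0).
#' @param base_contrast Baseline gray/white contrast (dimensionless).
#' @param site_amplitude Per-lobe site-offset amplitude on the contrast.
#' @param age_coef Per-lobe age coefficient on the contrast (per year).
#' @param gm_noise_sd Noise SD on the gray intensity.
#' @param contrast_noise_sd Noise SD on the contrast.
#' @param n_sites Number of sites.
#' @param seed Integer seed.
#' @return data.frame with columns `subject_id`, `lobe`, `gm_intensity`,
#'   `wm_intensity`; exactly 4 rows per subject.
#' @export
simulate_lobe_intensities <- function(records,
                                      base_gm = c(100, 98, 102, 105),
                                      base_contrast = 0.25,
                                      site_amplitude = c(0, 0.03, 0, 0),
                                      age_coef = c(0, 0, -0.0015, 0),
                                      gm_noise_sd = 1.0,
                                      contrast_noise_sd = 0.01,
                                      n_sites = 6L,
                                      seed = 1L) {
  stopifnot(length(base_gm) == 4L, all(base_gm > 0),
            length(site_amplitude) == 4L, length(age_coef) == 4L,
            gm_noise_sd >= 0, contrast_noise_sd >= 0)
  set.seed(as.integer(seed))
  n <- nrow(records)
  rows <- vector("list", 4L)
  for (l in seq_along(LOBES)) {
    gm_int <- base_gm[l] + rnorm(n, 0, gm_noise_sd)
    site_off <- site_offset_vector(n_sites, site_amplitude[l])[
      site_index(records$site)]
    C <- base_contrast + site_off + age_coef[l] * records$age +
      rnorm(n, 0, contrast_noise_sd)
    wm_int <- gm_int * (1 + C)
    rows[[l]] <- data.frame(subject_id = records$subject_id,
                            lobe = LOBES[l],
                            gm_intensity = gm_int,
                            wm_intensity = wm_int,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (any(out$gm_intensity <= 0) || any(out$wm_intensity <= 0))
    stop("parameters produced nonpositive intensities")
  out <- out[order(match(out$subject_id, records$subject_id),
                   match(out$lobe, LOBES)), ]
  rownames(out) <- NULL
  out
}
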