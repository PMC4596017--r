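#' Default run configuration
#'
#' Returns the full configuration for a pipeline run as a nested list.
#' Every tunable of the analysis is a key here; [write_config()] /
#' [read_config()] round-trip the object through YAML unchanged.
#'
#' Per-lobe parameters are unnamed numeric vectors in the canonical lobe
#' order frontal, temporal, parietal, occipital. Resolution probabilities
#' are in the order of `resolutions`.
#'
#' @param master_seed Integer master seed. All randomness in a run is a
#'   pure function of this seed: each stage draws from a named substream
#'   derived from it (see [substream_seed()]).
#' @return A list of class `devoclust_config`.
#' @export
default_config <- function(master_seed = 1L) {
  cfg <- list(
    master_seed = as.integer(master_seed),

    ## cohort ----------------------------------------------------------
    cohort = list(
      n_per_bin = 90L,
      bin_edges = c(4, 8, 10.5, 13.5, 18.5),
      n_sites   = 6L,
      resolutions = c(1.0, 1.5, 3.0),
      # sampling probabilities over `resolutions`; the youngest bin is
      # more likely to carry coarse voxels, mirroring multi-site
      # pediatric acquisitions where faster (coarser) protocols are used
      # for the youngest children
      res_probs_youngest = c(0.6, 0.2, 0.2),
      res_probs_older    = c(0.8, 0.15, 0.05)
    ),

    ## ground-truth atlas ----------------------------------------------
    atlas = list(
      grid = c(32L, 32L, 32L),
      voxel_size = 4,          # mm, isotropic
      k_gm = 4L,
      k_wm = 4L,
      baseline_gm = 0.7,       # modulated tissue amount, arbitrary units
      baseline_wm = 0.7,
      # per-bin slope draws (tissue amount per year); ranges allow the
      # mixed-sign profiles seen in development (gray mostly shrinking,
      # white mostly growing, with occasional sign flips in single bins)
      slope_range_gm = c(-0.04, 0.01),
      slope_range_wm = c(-0.01, 0.04),
      min_slope_sep = 0.04,    # Euclidean separation between region profiles
      # per-voxel within-region slope heterogeneity (fixed across
      # subjects), emulating the within-cluster slope spread of real data
      slope_jitter_sd = 0.0075
    ),

    ## map simulation ---------------------------------------------------
    effects = list(
      gender_offset = 0.01,        # added for males inside tissue regions
      site_amplitude = 0.03,       # site offsets span +/- this, zero-sum
      site_sensitive_gm = 1L,      # regions carrying the site/resolution
      site_sensitive_wm = 1L,      # offsets; elsewhere site effects are 0
      resolution_coef = -0.005,    # tissue amount per mm of voxel size
      noise_sd = 0.02,
      fwhm = 8                     # mm, Gaussian smoothing kernel
    ),

    ## principal-direction eigenvalue maps ------------------------------
    eigen = list(
      dominance = 0.8,
      noise_sd  = 0.05
    ),

    ## per-lobe native-intensity tables ---------------------------------
    lobes = list(
      base_gm = c(100, 98, 102, 105),     # arbitrary scanner units
      base_contrast = 0.25,
      # per-lobe site amplitude for the contrast C; only the temporal
      # lobe carries a site effect by default
      site_amplitude = c(0, 0.03, 0, 0),
      age_coef = c(0, 0, -0.0015, 0),     # contrast units per year
      gm_noise_sd = 1.0,
      contrast_noise_sd = 0.01
    ),

    ## analysis ----------------------------------------------------------
    analysis = list(
      mask_threshold = 0.4,
      eigen_threshold = 0.4,
      alpha = 0.001,               # uncorrected voxelwise screen
      k_range = 2:10,
      k_final = 4L,
      restarts = 10L,
      silhouette_subsample = 0L,   # 0 = use all rows
      dilate_radius = 1L,
      outlier_mad_mult = 3,
      adjustment_modes = c("proportional", "ancova")
    ),

    ## output -------------------------------------------------------------
    output = list(
      save_subject_maps = FALSE,
      gzip = FALSE
    )
  )
  class(cfg) <- c("devoclust_config", "list")
  cfg
}

#' Derive a per-stage substream seed from the master seed
#'
#' Keeps every stage's randomness independent and regenerable on its own
#' while remaining a pure function of the master seed.
#'
#' @param master_seed Integer master seed.
#' @param stage Stage name, one of `"cohort"`, `"atlas"`, `"maps"`,
#'   `"eigen"`, `"intensities"`, `"cluster"`.
#' @return An integer seed in `[0, 2^31)`.
#' @export
substream_seed <- function(master_seed, stage) {
  offsets <- c(cohort = 1L, atlas = 2L, maps = 3L, eigen = 4L,
               intensities = 5L, cluster = 6L)
  stage <- match.arg(stage, names(offsets))
  as.integer((as.double(master_seed) * 7919 + offsets[[stage]] * 104729) %%
               2147483647)
}

#' Write / read a run configuration as YAML
#'
#' @param config A configuration list as returned by [default_config()].
#' @param path File path of the YAML document.
#' @return `read_config()` returns the configuration list; `write_config()`
#'   returns `path` invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(is.list(config))
  x <- unclass(config)
  yaml::write_yaml(x, path, precision = 15L)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  # yaml reads 2:10 style sequences back as integer vectors already;
  # restore the class tag only
  class(cfg) <- c("devoclust_config", "list")
  cfg
}
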