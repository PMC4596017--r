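# Shared plumbing for the numbered analysis scripts.
#
# Every script is deterministic given the master seed below, so any script
# can be run on its own: expensive intermediates (the simulated maps) are
# cached under results/cache/ and regenerated when absent.

library(devoclust)

MASTER_SEED <- as.integer(Sys.getenv("DEVOCLUST_SEED", "1"))
CFG <- default_config(MASTER_SEED)

res_dir <- function(...) {
  d <- file.path("results", ...)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}

# cohort, atlas and maps are pure functions of the config; the maps cache
# only saves the ~10 s regeneration cost
study_inputs <- function(cfg = CFG) {
  cohort <- generate_cohort(
    n_per_bin = cfg$cohort$n_per_bin, bin_edges = cfg$cohort$bin_edges,
    n_sites = cfg$cohort$n_sites,
    seed = substream_seed(cfg$master_seed, "cohort"),
    resolutions = cfg$cohort$resolutions,
    res_probs_youngest = cfg$cohort$res_probs_youngest,
    res_probs_older = cfg$cohort$res_probs_older)
  atlas <- generate_atlas(
    grid = cfg$atlas$grid, k_gm = cfg$atlas$k_gm, k_wm = cfg$atlas$k_wm,
    seed = substream_seed(cfg$master_seed, "atlas"),
    voxel_size = cfg$atlas$voxel_size,
    baseline_gm = cfg$atlas$baseline_gm,
    baseline_wm = cfg$atlas$baseline_wm,
    slope_range_gm = cfg$atlas$slope_range_gm,
    slope_range_wm = cfg$atlas$slope_range_wm,
    min_slope_sep = cfg$atlas$min_slope_sep,
    slope_jitter_sd = cfg$atlas$slope_jitter_sd)
  cache <- file.path(res_dir("cache"), sprintf("maps_seed%d.rds", cfg$master_seed))
  if (file.exists(cache)) {
    maps <- readRDS(cache)
  } else {
    maps <- simulate_cohort_maps(cohort, atlas, cfg$effects,
                                 seed = substream_seed(cfg$master_seed, "maps"),
                                 bin_edges = cfg$cohort$bin_edges,
                                 n_sites = cfg$cohort$n_sites)
    saveRDS(maps, cache)
  }
  list(cohort = cohort, atlas = atlas, maps = maps)
}

study_masks <- function(inputs, cfg = CFG) {
  build_masks(mean_map(inputs$maps$gm, inputs$atlas$grid),
              mean_map(inputs$maps$wm, inputs$atlas$grid),
              cfg$analysis$mask_threshold)
}

study_betas <- function(inputs, masks, covariates = c("gender", "site",
                                                      "resolution")) {
  out <- list()
  for (t in c("gm", "wm")) {
    fits <- lapply(sort(unique(inputs$cohort$age_bin)), function(b) {
      in_bin <- inputs$cohort$age_bin == b
      fit_bin_glm(inputs$maps[[t]][in_bin, , drop = FALSE],
                  inputs$cohort[in_bin, ], masks[[t]],
                  covariates = covariates)
    })
    out[[t]] <- list(fits = fits, beta = age_beta_matrix(fits))
  }
  out
}

cluster_seed <- function(cfg = CFG) substream_seed(cfg$master_seed, "cluster")
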