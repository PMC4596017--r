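#' Run the full analysis pipeline
#'
#' Executes every stage in dependency order on a synthetic cohort:
#' cohort and ground-truth atlas generation, map simulation, mask
#' construction, the squared-distance outlier screen, per-bin voxelwise
#' age models for both tissues, silhouette scans and k-means clustering
#' of the slope matrices, gray-white cluster pairing by adjacency,
#' white-matter direction profiling, per-lobe image-contrast QC, site
#' and resolution F-contrasts, a covariate-sensitivity comparison
#' (models with vs without site/resolution covariates), and total-volume
#' adjustment variants. All artifacts are written under `out_dir` and a
#' manifest with per-file checksums is returned; rerunning with the same
#' configuration reproduces every output bit-identically.
#'
#' @param config Configuration list from [default_config()].
#' @param out_dir Output directory (created if missing).
#' @param quiet Suppress stage messages.
#' @return Invisibly, a list with every stage's in-memory result
#'   (cohort, atlas, masks, fits, beta matrices, scans, solutions,
#'   summaries, pairing, recovery metrics, direction profiles, contrast
#'   report, F-contrasts, sensitivity comparisons) plus the `manifest`.
#' @export
run_pipeline <- function(config = default_config(), out_dir,
                         quiet = FALSE) {
  stopifnot(is.list(config))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message("[devoclust] ", ...)
  ms <- config$master_seed
  vx <- config$atlas$voxel_size
  edges <- config$cohort$bin_edges
  ext <- if (isTRUE(config$output$gzip)) ".nii.gz" else ".nii"
  vol_path <- function(name) file.path(out_dir, paste0(name, ext))
  res <- list(config = config)

  write_config(config, file.path(out_dir, "config.yaml"))

  ## cohort -----------------------------------------------------------
  say("cohort: ", 4 * config$cohort$n_per_bin, " subjects, 4 bins, ",
      config$cohort$n_sites, " sites")
  cohort <- generate_cohort(
    n_per_bin = config$cohort$n_per_bin, bin_edges = edges,
    n_sites = config$cohort$n_sites,
    seed = substream_seed(ms, "cohort"),
    resolutions = config$cohort$resolutions,
    res_probs_youngest = config$cohort$res_probs_youngest,
    res_probs_older = config$cohort$res_probs_older)
  write_table(cohort, file.path(out_dir, "participants.tsv"))
  res$cohort <- cohort

  ## atlas -------------------------------------------------------------
  say("atlas: ", config$atlas$k_gm, " GM + ", config$atlas$k_wm,
      " WM regions on a ", paste(config$atlas$grid, collapse = "x"),
      " grid")
  atlas <- generate_atlas(
    grid = config$atlas$grid, k_gm = config$atlas$k_gm,
    k_wm = config$atlas$k_wm, seed = substream_seed(ms, "atlas"),
    voxel_size = vx, n_bins = length(edges) - 1L,
    baseline_gm = config$atlas$baseline_gm,
    baseline_wm = config$atlas$baseline_wm,
    slope_range_gm = config$atlas$slope_range_gm,
    slope_range_wm = config$atlas$slope_range_wm,
    min_slope_sep = config$atlas$min_slope_sep,
    slope_jitter_sd = config$atlas$slope_jitter_sd)
  write_volume(atlas$gm_labels, vol_path("atlas_gm_labels"), vx)
  write_volume(atlas$wm_labels, vol_path("atlas_wm_labels"), vx)
  for (t in c("gm", "wm"))
    write_table(data.frame(region = seq_len(nrow(atlas$slopes[[t]])),
                           atlas$slopes[[t]]),
                file.path(out_dir, paste0("atlas_slopes_", t, ".tsv")))
  write_table(data.frame(region = seq_along(atlas$wm_direction),
                         direction = atlas$wm_direction,
                         partner_gm = atlas$wm_partner_gm),
              file.path(out_dir, "atlas_wm_directions.tsv"))
  res$atlas <- atlas

  ## maps --------------------------------------------------------------
  say("maps: simulating ", nrow(cohort), " subjects x 2 tissues ",
      "(FWHM = ", config$effects$fwhm, " mm, noise sd = ",
      config$effects$noise_sd, ")")
  maps <- simulate_cohort_maps(cohort, atlas, config$effects,
                               seed = substream_seed(ms, "maps"),
                               bin_edges = edges,
                               n_sites = config$cohort$n_sites)
  mean_maps <- list(gm = mean_map(maps$gm, atlas$grid),
                    wm = mean_map(maps$wm, atlas$grid))
  write_volume(mean_maps$gm, vol_path("mean_gm"), vx)
  write_volume(mean_maps$wm, vol_path("mean_wm"), vx)
  if (isTRUE(config$output$save_subject_maps)) {
    dir.create(file.path(out_dir, "subjects"), showWarnings = FALSE)
    for (s in seq_len(nrow(cohort))) for (t in c("gm", "wm"))
      write_volume(array(maps[[t]][s, ], atlas$grid),
                   file.path(out_dir, "subjects",
                             paste0(cohort$subject_id[s], "_", t, ext)), vx)
  }

  ## masks (explicit, disjoint, threshold per the mask rule) -----------
  masks <- build_masks(mean_maps$gm, mean_maps$wm,
                       config$analysis$mask_threshold)
  say("masks: GM ", sum(masks$gm), " voxels, WM ", sum(masks$wm),
      " voxels at threshold ", config$analysis$mask_threshold)
  write_volume(masks$gm, vol_path("mask_gm"), vx)
  write_volume(masks$wm, vol_path("mask_wm"), vx)
  res$masks <- masks

  ## outlier screen ----------------------------------------------------
  outliers <- list()
  for (t in c("gm", "wm")) for (b in sort(unique(cohort$age_bin))) {
    in_bin <- cohort$age_bin == b
    o <- detect_outliers(maps[[t]][in_bin, , drop = FALSE], masks[[t]],
                         config$analysis$outlier_mad_mult)
    o$subject_id <- cohort$subject_id[in_bin]
    outliers[[paste(t, b)]] <- cbind(tissue = t, bin = b, o)
  }
  outliers <- do.call(rbind, outliers)
  rownames(outliers) <- NULL
  write_table(outliers, file.path(out_dir, "outliers.tsv"))
  say("outlier screen: ", sum(outliers$flagged), " flagged")
  res$outliers <- outliers

  ## per-bin GLMs and beta matrices ------------------------------------
  fits <- list(); betas <- list()
  for (t in c("gm", "wm")) {
    tf <- list()
    for (b in sort(unique(cohort$age_bin))) {
      in_bin <- cohort$age_bin == b
      tf[[b]] <- fit_bin_glm(maps[[t]][in_bin, , drop = FALSE],
                             cohort[in_bin, ], masks[[t]])
      write_volume(tf[[b]]$slope_map,
                   vol_path(sprintf("slope_%s_bin%d", t, b)), vx)
    }
    fits[[t]] <- tf
    betas[[t]] <- age_beta_matrix(tf)
    write_table(data.frame(voxel_index = betas[[t]]$voxel_index,
                           betas[[t]]$beta),
                file.path(out_dir, paste0("beta_", t, ".tsv")))
  }
  say("age models: per-bin slopes fitted on mean-centered age + gender",
      " + site + resolution")
  res$fits <- fits; res$betas <- betas

  ## clustering --------------------------------------------------------
  kseed <- substream_seed(ms, "cluster")
  scans <- list(); solutions <- list(); summaries <- list()
  for (t in c("gm", "wm")) {
    scans[[t]] <- silhouette_scan(
      betas[[t]], k_range = config$analysis$k_range,
      restarts = config$analysis$restarts,
      seed = kseed + match(t, c("gm", "wm")) * 100L,
      subsample = config$analysis$silhouette_subsample)
    write_table(data.frame(k = scans[[t]]$k,
                           mean_silhouette = scans[[t]]$silhouette),
                file.path(out_dir, paste0("silhouette_", t, ".tsv")))
    kf <- config$analysis$k_final
    solutions[[t]] <- scans[[t]]$solutions[[as.character(kf)]]
    if (is.null(solutions[[t]]))
      solutions[[t]] <- kmeans_cluster(betas[[t]], kf,
                                       config$analysis$restarts,
                                       seed = kseed + kf)
    lab_map <- embed_in_lattice(solutions[[t]]$labels, masks[[t]],
                                fill = 0)
    storage.mode(lab_map) <- "integer"
    res[[paste0("labels_", t)]] <- lab_map
    write_volume(lab_map, vol_path(paste0("clusters_", t)), vx)
    write_table(data.frame(cluster = seq_len(kf),
                           solutions[[t]]$centroids),
                file.path(out_dir, paste0("centroids_", t, ".tsv")))
    summaries[[t]] <- cluster_slope_summary(solutions[[t]], betas[[t]])
    write_table(summaries[[t]],
                file.path(out_dir, paste0("cluster_summary_", t, ".tsv")))
    say("clustering ", t, ": silhouette peak at k = ", scans[[t]]$best_k,
        "; final solution at k = ", kf)
  }
  res$scans <- scans; res$solutions <- solutions
  res$summaries <- summaries

  ## trajectories -------------------------------------------------------
  traj <- list()
  for (t in c("gm", "wm")) for (c in seq_len(config$analysis$k_final)) {
    sl <- summaries[[t]]$mean_slope[summaries[[t]]$cluster == c]
    tr <- trajectory_from_slopes(sl, edges,
                                 anchor = atlas$baselines[[t]])
    traj[[paste(t, c)]] <- data.frame(tissue = t, cluster = c,
                                      age = tr$knot_ages,
                                      value = tr$knot_values)
  }
  write_table(do.call(rbind, traj), file.path(out_dir, "trajectories.tsv"))

  ## pairing ------------------------------------------------------------
  pairing <- pair_clusters(res$labels_gm, res$labels_wm,
                           config$analysis$dilate_radius)
  write_table(pairing$pairs, file.path(out_dir, "pairing.tsv"))
  say("pairing: ", paste(sprintf("GM%d-WM%d", pairing$pairs$gm_cluster,
                                 pairing$pairs$wm_cluster),
                         collapse = ", "))
  res$pairing <- pairing

  ## recovery against ground truth --------------------------------------
  recovery <- list()
  for (t in c("gm", "wm")) {
    truth <- (if (t == "gm") atlas$gm_labels else
                atlas$wm_labels)[masks[[t]]]
    recovery[[t]] <- data.frame(
      tissue = t,
      ari = mclust::adjustedRandIndex(solutions[[t]]$labels, truth),
      best_k = scans[[t]]$best_k)
  }
  recovery <- do.call(rbind, recovery)
  rownames(recovery) <- NULL
  write_table(recovery, file.path(out_dir, "recovery.tsv"))
  say("recovery: GM ARI ", round(recovery$ari[1], 3), ", WM ARI ",
      round(recovery$ari[2], 3))
  res$recovery <- recovery

  ## direction profile ---------------------------------------------------
  eig <- simulate_eigenvalue_maps(atlas, config$eigen$dominance,
                                  config$eigen$noise_sd,
                                  seed = substream_seed(ms, "eigen"))
  for (d in DIRECTIONS) write_volume(eig[[d]],
                                     vol_path(paste0("eigen_", d)), vx)
  profile <- dominant_direction_profile(res$labels_wm, eig,
                                        config$analysis$eigen_threshold)
  write_table(profile, file.path(out_dir, "direction_profile.tsv"))
  sorted_rows <- list()
  for (c in seq_len(config$analysis$k_final)) {
    sm <- sorted_eigen_matrix(res$labels_wm, eig,
                              config$analysis$eigen_threshold, c)
    if (nrow(sm$values))
      sorted_rows[[c]] <- data.frame(cluster = c,
                                     voxel_index = sm$voxel_index,
                                     direction = sm$direction,
                                     sm$values)
  }
  write_table(do.call(rbind, sorted_rows),
              file.path(out_dir, "sorted_eigen.tsv"))
  res$eigen <- eig; res$direction_profile <- profile

  ## image-contrast QC ----------------------------------------------------
  intens <- simulate_lobe_intensities(
    cohort, base_gm = config$lobes$base_gm,
    base_contrast = config$lobes$base_contrast,
    site_amplitude = config$lobes$site_amplitude,
    age_coef = config$lobes$age_coef,
    gm_noise_sd = config$lobes$gm_noise_sd,
    contrast_noise_sd = config$lobes$contrast_noise_sd,
    n_sites = config$cohort$n_sites,
    seed = substream_seed(ms, "intensities"))
  write_table(intens, file.path(out_dir, "lobe_intensities.tsv"))
  contr <- compute_contrast(intens)
  write_table(contr, file.path(out_dir, "contrast.tsv"))
  areport <- do.call(rbind, c(
    list(contrast_anova(contr, cohort, "full")),
    lapply(sort(unique(cohort$age_bin)),
           function(b) contrast_anova(contr, cohort, b))))
  write_table(areport, file.path(out_dir, "contrast_anova.tsv"))
  res$lobe_intensities <- intens
  res$contrast <- contr; res$contrast_anova <- areport

  ## site / resolution F-contrasts ----------------------------------------
  fcontrasts <- list(); fsum <- list()
  for (t in c("gm", "wm")) for (e in c("site", "resolution")) {
    fc <- f_contrast(maps[[t]], cohort, masks[[t]], e,
                     config$analysis$alpha)
    write_volume(fc$f_map, vol_path(sprintf("F_%s_%s", t, e)), vx)
    write_volume(fc$p_map, vol_path(sprintf("p_%s_%s", t, e)), vx)
    fcontrasts[[paste(t, e)]] <- fc
    fsum[[paste(t, e)]] <- data.frame(
      tissue = t, effect = e, df1 = fc$df1, df2 = fc$df2,
      alpha = fc$alpha,
      n_suprathreshold = sum(fc$suprathreshold),
      suprathreshold_fraction = fc$suprathreshold_fraction)
  }
  fsum <- do.call(rbind, fsum)
  rownames(fsum) <- NULL
  write_table(fsum, file.path(out_dir, "fcontrast_summary.tsv"))
  say("F-contrasts at alpha = ", config$analysis$alpha, " (uncorrected)")
  res$fcontrasts <- fcontrasts; res$fcontrast_summary <- fsum

  ## covariate sensitivity: cluster without site/resolution ---------------
  sens <- list()
  for (t in c("gm", "wm")) {
    tf <- list()
    for (b in sort(unique(cohort$age_bin))) {
      in_bin <- cohort$age_bin == b
      tf[[b]] <- fit_bin_glm(maps[[t]][in_bin, , drop = FALSE],
                             cohort[in_bin, ], masks[[t]],
                             covariates = "gender")
    }
    beta_nc <- age_beta_matrix(tf)
    sol_nc <- kmeans_cluster(beta_nc, config$analysis$k_final,
                             config$analysis$restarts,
                             seed = kseed + 500L +
                               match(t, c("gm", "wm")))
    cmp <- compare_solutions(solutions[[t]], sol_nc, masks[[t]])
    if (!is.null(cmp$agreement_map)) {
      am <- cmp$agreement_map
      am[is.na(am)] <- 0
      storage.mode(am) <- "integer"
      write_volume(am, vol_path(paste0("covariate_agreement_", t)), vx)
    }
    sens[[t]] <- data.frame(tissue = t, comparison = "no_site_resolution",
                            ari = cmp$ari,
                            min_dice = min(cmp$dice, na.rm = TRUE))
  }
  res$covariate_sensitivity <- do.call(rbind, sens)
  rownames(res$covariate_sensitivity) <- NULL

  ## total-volume adjustment variants --------------------------------------
  adj <- list()
  for (mode in config$analysis$adjustment_modes) for (t in c("gm", "wm")) {
    af <- fit_with_volume_adjustment(maps[[t]], cohort, masks[[t]],
                                     mode, vx)
    beta_a <- age_beta_matrix(af)
    sol_a <- kmeans_cluster(beta_a, config$analysis$k_final,
                            config$analysis$restarts,
                            seed = kseed + 900L +
                              match(mode, c("proportional", "ancova")) *
                              10L + match(t, c("gm", "wm")))
    cmp <- compare_solutions(solutions[[t]], sol_a)
    adj[[paste(mode, t)]] <- data.frame(tissue = t, mode = mode,
                                        ari = cmp$ari)
  }
  res$adjustment_sensitivity <- do.call(rbind, adj)
  rownames(res$adjustment_sensitivity) <- NULL
  sens_tab <- rbind(
    data.frame(tissue = res$covariate_sensitivity$tissue,
               comparison = res$covariate_sensitivity$comparison,
               ari = res$covariate_sensitivity$ari),
    data.frame(tissue = res$adjustment_sensitivity$tissue,
               comparison = res$adjustment_sensitivity$mode,
               ari = res$adjustment_sensitivity$ari))
  write_table(sens_tab, file.path(out_dir, "sensitivity.tsv"))
  say("sensitivity: clustering vs model variants, min ARI ",
      round(min(sens_tab$ari), 3))

  ## manifest ---------------------------------------------------------------
  files <- sort(list.files(out_dir, recursive = TRUE))
  files <- files[files != "manifest.yaml"]
  sums <- tools::md5sum(file.path(out_dir, files))
  manifest <- list(
    package_version = as.character(utils::packageVersion("devoclust")),
    master_seed = ms,
    config_md5 = unname(tools::md5sum(file.path(out_dir, "config.yaml"))),
    files = as.list(setNames(unname(sums), files)))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  res$manifest <- manifest
  say("done: ", length(files), " artifacts in ", out_dir)
  invisible(res)
}
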