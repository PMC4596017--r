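#!/usr/bin/env Rscript
# Stage 2: explicit masks, outlier screen, and per-bin voxelwise age
# models.
#
# Masks threshold the mean tissue maps at >0.4 with a strict tie rule
# that keeps gray and white masks disjoint. Within each bin, subjects
# are screened by squared distance to the bin mean map. Each bin then
# gets an OLS model per masked voxel: tissue amount ~ mean-centered age
# + gender + site (one indicator per site) + linear resolution; the age
# coefficients across the four bins form the voxel-by-bin beta matrix
# that later stages cluster.

source(file.path("analysis", "helpers.R"))

inp <- study_inputs()
masks <- study_masks(inp)
out <- res_dir("glm")
vx <- inp$atlas$voxel_size

write_volume(masks$gm, file.path(out, "mask_gm.nii"), vx)
write_volume(masks$wm, file.path(out, "mask_wm.nii"), vx)
cat(sprintf("masks: %d gray and %d white voxels (threshold %.1f)\n",
            sum(masks$gm), sum(masks$wm), CFG$analysis$mask_threshold))

outliers <- do.call(rbind, lapply(c("gm", "wm"), function(t) {
  do.call(rbind, lapply(1:4, function(b) {
    in_bin <- inp$cohort$age_bin == b
    o <- detect_outliers(inp$maps[[t]][in_bin, , drop = FALSE], masks[[t]],
                         CFG$analysis$outlier_mad_mult)
    o$subject_id <- inp$cohort$subject_id[in_bin]
    cbind(tissue = t, bin = b, o)
  }))
}))
write_table(outliers, file.path(out, "outliers.tsv"))
cat(sprintf("outlier screen: %d of %d subject x tissue x bin entries flagged\n",
            sum(outliers$flagged), nrow(outliers)))

betas <- study_betas(inp, masks)
for (t in c("gm", "wm")) {
  for (b in 1:4)
    write_volume(betas[[t]]$fits[[b]]$slope_map,
                 file.path(out, sprintf("slope_%s_bin%d.nii", t, b)), vx)
  write_table(data.frame(voxel_index = betas[[t]]$beta$voxel_index,
                         betas[[t]]$beta$beta),
              file.path(out, paste0("beta_", t, ".tsv")))
  rng <- range(betas[[t]]$beta$beta)
  cat(sprintf("%s: beta matrix %d x 4, slopes in [%.4f, %.4f] per year\n",
              t, nrow(betas[[t]]$beta$beta), rng[1], rng[2]))
}
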