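#!/usr/bin/env Rscript
# Stage 1: build the synthetic study.
#
# Generates the cohort table (360 subjects in four age bins of 90, 45
# male / 45 female each, six sites, mixed acquisition resolutions), the
# ground-truth atlas (4 gray + 4 white regions with per-bin slope
# profiles, paired by adjacency, each white region with a dominant fiber
# direction), the per-subject modulated tissue maps (8 mm smoothing,
# additive gender/site/resolution effects, Gaussian noise), the
# principal-direction eigenvalue maps, and the per-lobe intensity table.

source(file.path("analysis", "helpers.R"))

inp <- study_inputs()
out <- res_dir("data")
vx <- inp$atlas$voxel_size

write_table(inp$cohort, file.path(out, "participants.tsv"))
write_volume(inp$atlas$gm_labels, file.path(out, "atlas_gm_labels.nii"), vx)
write_volume(inp$atlas$wm_labels, file.path(out, "atlas_wm_labels.nii"), vx)
for (t in c("gm", "wm"))
  write_table(data.frame(region = seq_len(nrow(inp$atlas$slopes[[t]])),
                         inp$atlas$slopes[[t]]),
              file.path(out, paste0("atlas_slopes_", t, ".tsv")))
write_table(data.frame(region = 1:4, direction = inp$atlas$wm_direction,
                       partner_gm = inp$atlas$wm_partner_gm),
            file.path(out, "atlas_wm_directions.tsv"))
write_volume(mean_map(inp$maps$gm, inp$atlas$grid),
             file.path(out, "mean_gm.nii"), vx)
write_volume(mean_map(inp$maps$wm, inp$atlas$grid),
             file.path(out, "mean_wm.nii"), vx)

eig <- simulate_eigenvalue_maps(inp$atlas, CFG$eigen$dominance,
                                CFG$eigen$noise_sd,
                                seed = substream_seed(MASTER_SEED, "eigen"))
for (d in c("x", "y", "z"))
  write_volume(eig[[d]], file.path(out, paste0("eigen_", d, ".nii")), vx)

intens <- simulate_lobe_intensities(
  inp$cohort, base_gm = CFG$lobes$base_gm,
  base_contrast = CFG$lobes$base_contrast,
  site_amplitude = CFG$lobes$site_amplitude,
  age_coef = CFG$lobes$age_coef, gm_noise_sd = CFG$lobes$gm_noise_sd,
  contrast_noise_sd = CFG$lobes$contrast_noise_sd,
  n_sites = CFG$cohort$n_sites,
  seed = substream_seed(MASTER_SEED, "intensities"))
write_table(intens, file.path(out, "lobe_intensities.tsv"))

cat(sprintf(
  "Simulated %d subjects (%d per bin, %d sites) on a %s grid;\n",
  nrow(inp$cohort), CFG$cohort$n_per_bin, CFG$cohort$n_sites,
  paste(inp$atlas$grid, collapse = "x")),
  sprintf("gray regions span %d voxels, white %d; outputs in %s\n",
          sum(inp$atlas$gm_labels > 0), sum(inp$atlas$wm_labels > 0), out))
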