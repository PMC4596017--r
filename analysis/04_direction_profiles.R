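#!/usr/bin/env Rscript
# Stage 4: dominant fiber direction of the white matter clusters.
#
# Each white cluster is intersected with the three principal-direction
# eigenvalue maps; voxels whose largest eigenvalue reaches 0.4 are kept
# and assigned to their argmax direction (x right-left, y
# anterior-posterior, z superior-inferior). The per-cluster proportions
# quantify directional bias; the sorted eigenvalue matrix reproduces the
# voxelwise picture behind them.

source(file.path("analysis", "helpers.R"))

inp <- study_inputs()
out <- res_dir("direction")

clusters_file <- file.path("results", "clustering", "clusters_wm.nii")
if (!file.exists(clusters_file))
  stop("run analysis/03_cluster_slopes.R first: ", clusters_file,
       " is missing")
labels <- read_volume(clusters_file)

eig <- simulate_eigenvalue_maps(inp$atlas, CFG$eigen$dominance,
                                CFG$eigen$noise_sd,
                                seed = substream_seed(MASTER_SEED, "eigen"))

prof <- dominant_direction_profile(labels, eig, CFG$analysis$eigen_threshold)
write_table(prof, file.path(out, "direction_profile.tsv"))
for (c in seq_len(max(labels))) {
  row <- prof[prof$cluster == c, ]
  props <- c(x = row$prop_x, y = row$prop_y, z = row$prop_z)
  cat(sprintf("WM cluster %d: %d/%d voxels retained; dominant %s (%.0f%%)\n",
              c, row$n_retained, row$n_voxels,
              names(which.max(props)), 100 * max(props)))
}

sorted_rows <- do.call(rbind, lapply(seq_len(max(labels)), function(c) {
  sm <- sorted_eigen_matrix(labels, eig, CFG$analysis$eigen_threshold, c)
  if (!nrow(sm$values)) return(NULL)
  data.frame(cluster = c, voxel_index = sm$voxel_index,
             direction = sm$direction, sm$values)
}))
write_table(sorted_rows, file.path(out, "sorted_eigen.tsv"))
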