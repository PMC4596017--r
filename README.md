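# devoclust

Data-driven clustering of developmental age slopes in gray and white
matter volume.

Across late childhood and adolescence, gray matter volume contracts
while white matter volume expands, and these changes are coordinated
across regions. `devoclust` is an R package plus analysis workflow for
characterizing that coordination from voxel-based morphometry (VBM)
inputs — spatially normalized, modulated tissue-amount maps — for
researchers studying structural covariance and brain development. The
restricted cohorts such studies use are replaced here by a fully
synthetic study generator with known ground truth, so the entire
pipeline is testable and reproducible on any machine.

## Method

With the cohort split into four age bins (4–8, 8–10.5, 10.5–13.5,
13.5–18.5 years), the pipeline:

1. fits, per bin and per masked voxel *v*, the OLS model
   `y_sv = β_v·(age_s − mean age) + γ_v·male_s + Σ_j δ_jv·site_js +
   ρ_v·res_s + ε_sv`,
   where β_v is the age slope (tissue amount per year); masks come from
   mean tissue maps thresholded at >0.4 with a strict tie rule that
   keeps gray and white masks disjoint;
2. collects the slopes into a voxels × bins matrix **B** per tissue and
   clusters its rows by k-means (squared Euclidean distance, 10
   restarts, batch + online phases), selecting k by the peak of
   Rousseeuw's mean silhouette over k = 2..10, then fixing k = 4 for
   both tissues so clusters can be paired;
3. pairs gray and white clusters by the score-maximizing bijection over
   dilated 26-neighborhood adjacency counts;
4. profiles each white cluster's dominant fiber direction from three
   principal-direction eigenvalue maps (retain voxels with max weight
   ≥ 0.4, assign to the argmax of x/y/z);
5. runs QC: a squared-distance outlier screen per bin, partial
   F-contrasts for site (multi-column) and resolution (single-column)
   effects at p < 0.001 uncorrected, total-volume model variants
   (proportional scaling, ANCOVA), and per-lobe gray/white image
   contrast `C = (I_WM − I_GM)/I_GM` tested against site and age.

The methods vignette
(`vignettes/developmental-volume-clustering.Rmd`) documents the model,
every default, and the design decisions.

## Quick start

```r
library(devoclust)
res <- run_pipeline(default_config(master_seed = 1L), "results/run1")
```

which logs, on this configuration:

```
[devoclust] cohort: 360 subjects, 4 bins, 6 sites
[devoclust] atlas: 4 GM + 4 WM regions on a 32x32x32 grid
[devoclust] maps: simulating 360 subjects x 2 tissues (FWHM = 8 mm, noise sd = 0.02)
[devoclust] masks: GM 3716 voxels, WM 3444 voxels at threshold 0.4
[devoclust] outlier screen: 19 flagged
[devoclust] age models: per-bin slopes fitted on mean-centered age + gender + site + resolution
[devoclust] clustering gm: silhouette peak at k = 4; final solution at k = 4
[devoclust] clustering wm: silhouette peak at k = 4; final solution at k = 4
[devoclust] pairing: GM1-WM1, GM2-WM2, GM3-WM4, GM4-WM3
[devoclust] recovery: GM ARI 1, WM ARI 1
[devoclust] F-contrasts at alpha = 0.001 (uncorrected)
[devoclust] done: 53 artifacts in results/run1
```

Reading the output: both silhouette scans peak at the generative four
clusters; the recovered voxel labels match the ground-truth regions
perfectly (adjusted Rand index 1.0 for both tissues); the adjacency
pairing links each white cluster to the gray cluster it develops
against (here GM3 pairs with WM4 and GM4 with WM3 — cluster numbering
is arbitrary, the bijection is what matters); and 19 of 720
subject × tissue × bin outlier-screen entries are flagged, all
coarse-resolution subjects. Artifacts (NIfTI label and slope maps, TSV
tables, a checksummed manifest) land in `results/run1`.

## The analysis workflow

The numbered scripts under `analysis/` run the same study stage by
stage, narrating what each finds and writing tables under `results/`:

```sh
Rscript analysis/01_simulate.R            # cohort, atlas, maps, eigenvalue maps
Rscript analysis/02_fit_age_models.R      # masks, outlier screen, per-bin GLMs
Rscript analysis/03_cluster_slopes.R      # silhouette scan, k = 4 solutions, pairing
Rscript analysis/04_direction_profiles.R  # dominant fiber directions
Rscript analysis/05_qc_site_resolution.R  # F-contrasts, model-variant stability
Rscript analysis/06_contrast_qc.R         # gray/white contrast ANOVAs
```

Stage 4, for example, prints:

```
WM cluster 1: 764/764 voxels retained; dominant z (100%)
WM cluster 2: 764/764 voxels retained; dominant x (100%)
WM cluster 3: 732/732 voxels retained; dominant x (100%)
WM cluster 4: 1184/1184 voxels retained; dominant y (100%)
```

i.e., each white cluster is dominated by a single principal direction,
as constructed; and stage 6 finds the injected temporal-lobe site
effect (F = 263.5, p < 0.001) and parietal age trend (F = 103.3) while
the unaffected lobes stay null. Set `DEVOCLUST_SEED` to rerun the whole
workflow under a different master seed.

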