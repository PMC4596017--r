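---
title: "Clustering developmental age slopes in gray and white matter volume"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clustering developmental age slopes in gray and white matter volume}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question and the approach

Across late childhood and adolescence, gray matter volume tends to
contract while white matter volume expands. These changes are not
uniform: sets of regions change together, forming developmental
covariance networks. `devoclust` implements a data-driven pipeline for
characterizing this coordination from voxel-based morphometry (VBM)
style inputs: spatially normalized, *modulated* tissue-amount maps, in
which each voxel's value is proportional to the local tissue volume it
represents.

The pipeline has five analytic stages:

1. **Per-bin voxelwise age models.** Because volume development is
   nonlinear over 4–18 years, the cohort is split into four age bins
   (4–8, 8–10.5, 10.5–13.5, 13.5–18.5 years) and a linear model is fitted
   per voxel *within* each bin.
2. **Slope-profile clustering.** The four per-bin age slopes at each
   voxel form a profile; k-means groups voxels with similar profiles,
   separately for gray and white matter, and the mean silhouette over
   k = 2..10 selects the number of clusters.
3. **Gray–white cluster pairing** by spatial adjacency.
4. **Directional profiling** of white matter clusters against
   principal-direction eigenvalue maps.
5. **Quality control:** a subject-level outlier screen, F-contrast
   screens for site and resolution effects, total-volume model variants,
   and a gray/white image-contrast analysis.

Because the cohorts this analysis is designed for are access-restricted,
the package ships a fully synthetic study generator with known ground
truth. The generator is a first-class, tested module: every downstream
stage can be validated by parameter recovery against the truth it
encodes.

## The voxelwise model

Within one age bin, with subjects $s = 1..n$ and a masked voxel $v$, the
tissue amount $y_{sv}$ is modeled by ordinary least squares as

$$y_{sv} = \beta_v\,(\mathrm{age}_s - \overline{\mathrm{age}}) +
  \gamma_v\,\mathrm{male}_s + \sum_j \delta_{jv}\,\mathrm{site}_{js} +
  \rho_v\,\mathrm{res}_s + \varepsilon_{sv},$$

where $\beta_v$ (tissue amount per year) is the quantity of interest.
Design choices, and why:

* **Age is mean-centered within the modeled sample.** The slope is
  invariant to centering; centering keeps the other columns
  interpretable.
* **Site uses cell-means coding** — one indicator per site and *no*
  separate intercept. The site block spans the intercept, so the fitted
  subspace (and therefore $\beta_v$ and all F-contrasts) is identical to
  reference coding with an intercept, while every site keeps its own
  mean. A rank check rejects degenerate designs and names the collinear
  columns.
* **Resolution** enters linearly (mm of isotropic voxel size),
  mean-centered by default; slopes are invariant to this choice too.
* **No voxel-level significance testing of $\beta_v$.** All masked
  voxels enter the clustering regardless of the significance of their
  age effect; the slopes are descriptive inputs, not test statistics.
* Classical (non-robust) residual variance, $\hat\sigma^2_v =
  \mathrm{RSS}_v / (n - p)$.

**Masks.** Explicit masks are built from mean tissue maps thresholded at
$> 0.4$, with a strict tie rule: a voxel joins the gray mask only if its
gray mean exceeds both the threshold *and* the white mean (and
symmetrically), so the two masks are disjoint by construction and exact
ties belong to neither.

**Outlier screen.** Within each bin, each subject's squared Euclidean
distance to the bin's voxelwise mean map is computed over the mask;
subjects beyond `median + 3 * MAD` are flagged (reported, never silently
dropped). On clean, acquisition-homogeneous synthetic bins this flags
nobody; in the default study the flagged entries are the
coarse-resolution subjects, which is informative rather than alarming.

## Clustering and model selection

The voxel-by-bin matrix of $\hat\beta$ values (one row per masked voxel,
one column per bin, in lexicographic voxel order with an exact inverse
index) is clustered by k-means with squared Euclidean distance on
**unstandardized** slopes — the bins share units, and standardizing would
inflate low-variance bins. A config flag allows per-column z-scoring for
sensitivity checks.

The optimizer is the standard two-phase scheme: Lloyd iterations from
random data rows (10 restarts by default), followed by an **online
phase** of single-point reassignments that uses the exact change in the
objective, including the centroid-shift factors $n/(n-1)$ and $n/(n+1)$.
The online phase matters: there exist small configurations where no
data-seeded Lloyd run can reach the global optimum, while a single
exact-gain move closes the gap. If a cluster empties during iteration,
its centroid is re-seeded at the point farthest from its assigned
centroid. The best restart by total within-cluster sum of squares wins;
everything is deterministic given the seed.

Model selection scans k = 2..10 and computes Rousseeuw's mean silhouette
(Euclidean distance, consistent with the squared-Euclidean objective;
singleton clusters score 0). Ties in the scan break toward the smallest
k. The silhouette can be computed on a row subsample for very large
masks (config key; the default uses all rows). Whatever the scan says,
the reported solution fixes **k = 4 for both tissues** so that gray and
white cluster sets can be paired one-to-one; the scan result is always
written alongside. With the default synthetic study both scans do peak
at 4.

## Pairing and solution comparison

Published analyses of this kind pair clusters by visual adjacency. The
package operationalizes this deterministically: each gray and each white
cluster mask is dilated by a configurable radius (default 1 voxel), the
adjacency score of a pair is the number of 26-neighborhood voxel
contacts between the dilated masks, and the returned pairing is the
score-maximizing bijection over all $k!$ permutations (exhaustive,
$k \le 10$; ties resolve toward lexicographic cluster order). If every
score is zero the result carries an `uninformative` flag. The method tag
records the operationalization.

`compare_solutions()` aligns two labelings of the same voxels by the
agreement-maximizing label permutation (exhaustive for $k \le 8$, greedy
beyond), then reports the adjusted Rand index (chance-corrected and
permutation-invariant), per-cluster Dice coefficients, and a voxelwise
agreement lattice.

## Directional profiling

White matter cluster labels are intersected with three co-registered
direction-weight volumes (x: right–left, y: anterior–posterior, z:
superior–inferior; values in [0,1]). Voxels whose *largest* weight is at
least 0.4 (inclusive) are retained; each is assigned to its argmax
direction, with exact ties broken in the fixed order x → y → z and
counted in a tie tally. A cluster with no retained voxel yields `NA`
proportions plus an `undefined` flag and a warning — never silent zeros.
The sorted eigenvalue matrix (rows grouped by dominant direction,
descending maximum within group, voxel coordinate as final tie-break)
reproduces the voxel-level picture deterministically. Any triple of
co-registered direction-weight volumes can be supplied; the synthetic
generator is simply the default source.

## Quality-control analyses

**Site and resolution F-contrasts.** A full-sample model (age, gender,
site, resolution) is fitted per masked voxel; a partial F compares it to
the model without the tested effect — for site this removes the whole
indicator block and substitutes a plain intercept (a multi-column,
"nonlinear" contrast, df1 = sites − 1), for resolution it drops one
column. Voxels with p < 0.001 (uncorrected, the conventional screening
threshold; configurable) form the suprathreshold map. No cluster-extent
or random-field correction is applied — these are screens, not
inference.

One property of this screen is worth knowing when reading its output on
the synthetic study: the full-sample model imposes a *single* linear age
term on data that are generatively piecewise-linear across bins. At
voxels with steep slope profiles this misspecification inflates the
residual variance and can mask the (small, uniform) resolution effect,
so the resolution suprathreshold fraction varies noticeably across
master seeds. That is a faithful property of full-range linear screens
on nonlinear development — and exactly why the primary analysis fits
per-bin models.

**Total-volume variants.** `proportional` divides each subject's map by
its total masked tissue volume, rescaled by the sample mean total so the
values keep tissue-amount units and slopes stay comparable across modes;
`ancova` appends mean-centered total volume as a nuisance column. In the
synthetic study proportional scaling leaves the clustering untouched
(ARI = 1 against the main model) while ANCOVA reshuffles it
substantially: total volume is itself strongly age-driven here, so
covarying it out re-expresses every slope relative to the global trend.
The package reports this honestly rather than smoothing it over.

**Image contrast.** Per subject and lobe, $C = (I_{WM} - I_{GM}) /
I_{GM}$ from native-space mean intensities; C is dimensionless and
scale-invariant. Per lobe, `C ~ site + age` is fitted and partial F
statistics for site (adjusting age) and age (adjusting site) are
reported for the full sample and within each bin, flagged as
uncorrected. Mask warping to native space is out of scope: the
synthetic generator emits the per-lobe intensity table directly, and
real data enter through the same TSV schema.

## The synthetic study

`generate_cohort()`, `generate_atlas()`, `simulate_cohort_maps()`,
`simulate_eigenvalue_maps()` and `simulate_lobe_intensities()` define
the study conditions. Defaults, with units and rationale:

* **Cohort:** 4 bins × 90 subjects, 45 male / 45 female per bin, edges
  4, 8, 10.5, 13.5, 18.5 years; ages uniform within bin (the least
  informative choice given only ranges and means); 6 sites assigned
  round-robin within bin then shuffled, so bins are site-balanced;
  isotropic resolutions {1.0, 1.5, 3.0} mm sampled with probabilities
  (0.6, 0.2, 0.2) in the youngest bin and (0.8, 0.15, 0.05) elsewhere,
  reproducing the tendency of the youngest children to carry coarser,
  faster acquisitions.
* **Atlas:** 32³ grid at a nominal 4 mm voxel size — a deliberately
  desk-scale stand-in for 1 mm acquisitions; grid and voxel size are
  config keys. 4 gray + 4 white regions as connected rectangular blocks
  in non-touching lattice cells; each cell stacks one gray and one white
  block along z with a shared face, giving the generative pairing. Block
  extents are drawn from a balanced band (60–80% of the usable cell
  extent) so regions of one tissue have comparable volumes — wildly
  unbalanced regions would turn k-means recovery into a size contest,
  which is not the regime the analysis addresses.
* **Slopes:** per-region per-bin slopes drawn uniformly from
  [−0.04, 0.01] (gray) and [−0.01, 0.04] (white) tissue-units/year —
  gray mostly shrinking, white mostly growing, sign flips in single bins
  allowed — rejection-sampled to a minimum Euclidean profile separation
  of 0.04 so that clustering is well posed. On top of the region
  profile, every voxel carries a fixed Gaussian deviation
  (`slope_jitter_sd = 0.0075`/year): real clusters show within-cluster
  slope spread comparable to the centroid magnitudes, and without it the
  synthetic data are degenerate (zero within-region variance), which
  makes silhouette selection latch onto smoothing-attenuated boundary
  shells instead of regions. The value keeps that shell displacement
  within about one within-cluster standard deviation while keeping
  centroid separation at roughly three, so label recovery stays
  near-perfect.
* **Maps:** voxel value = baseline (0.7) + voxel slope × (age − bin
  midpoint) + 0.01 for males + site offset + (−0.005/mm) × resolution +
  i.i.d. Gaussian noise (sd 0.02), smoothed with an 8 mm FWHM Gaussian
  and clipped at 0. Site offsets are zero-sum across sites (amplitude
  0.03) and applied only in a designated "site-sensitive" region per
  tissue, mimicking localized scanner effects; gender and resolution
  effects apply throughout the tissue.
* **Eigenvalue maps:** within each white region the assigned direction's
  weight is drawn near 0.8 and the other two near 0.1, with sd-0.05
  noise, clipped to [0,1]; background (including gray matter) is noise
  near 0.
* **Lobe intensities:** gray base intensities (100, 98, 102, 105) for
  frontal, temporal, parietal, occipital; base contrast 0.25; a
  temporal-lobe-only site effect (amplitude 0.03) and a small negative
  age trend in parietal contrast (−0.0015/year), echoing the pattern of
  findings such QC analyses typically surface.

**Smoothing details.** FWHM converts to voxels as
$\sigma = \mathrm{FWHM} / (2\sqrt{2\ln 2}) / \mathrm{voxel\ size}$,
truncated at 4σ; the separable kernel is applied per axis with
zero-padding (no boundary renormalization), matching common neuroimaging
smoothers; FWHM = 0 is the exact identity. The implementation is tested
against a direct triple-loop 3D convolution.

**What the generator does not emulate**, and therefore what passing
tests do *not* establish about real data: no raw T1 intensities,
segmentation, or registration (maps are born normalized and modulated);
no anatomical shape variability between subjects (all subjects share the
region supports, so real masks are fuzzier than synthetic ones); noise
is spatially white before smoothing, whereas real VBM residuals have
richer spatial structure; regions are rectangular; development is
exactly piecewise-linear with uniform ages. Recovery results on this
study validate the *pipeline's correctness*, not the neurobiology of any
particular cohort.

## Determinism and seeding

Every random quantity is a pure function of one master seed. Each stage
(cohort, atlas, maps, eigenvalue maps, intensities, clustering) draws
from a named substream derived from it, so stages can be regenerated
independently and the full pipeline is bit-reproducible: two runs with
the same configuration produce identical checksums for every NIfTI and
TSV artifact, which the manifest records.

## Problem sizes

The default study (360 subjects, 32³ grid, ~3,500–4,500 masked voxels
per tissue) runs end to end in well under a minute on one CPU; the
package's unit tests use further-reduced instances (16³ grids, 12–24
subjects) chosen so that each property is exercised at the smallest size
that is not degenerate. Silhouette scans dominate the cost at larger
masks (pairwise distances are O(m²)); the subsample config key is the
lever if masks grow by an order of magnitude.

## Known limitations

* The pairing operationalization (dilated contact counts) is one
  reasonable formalization of "adjacency"; others (centroid distance,
  boundary overlap fraction) could rank differently in edge cases.
* The silhouette is computed on the same matrix that was clustered;
  model selection is therefore descriptive, not inferential.
* The ANCOVA variant's sensitivity to global age trends (see above)
  means its clusters answer a different question — "which regions change
  relative to the global trend" — and should be read as such.
* Cross-sectional slopes are not longitudinal trajectories; the
  piecewise-linear "trajectory" curves are graphical integrations of
  bin-mean slopes from an arbitrary anchor, not growth curves.
* F-contrast screens use uncorrected voxelwise thresholds by design; no
  spatial inference is implemented.
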