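Package: devoclust
Title: Clustering of Developmental Age Slopes in Gray and White Matter Volume
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A voxel-based morphometry style analysis pipeline for studying
    coordinated development of gray and white matter volume across childhood
    and adolescence. Fits voxelwise linear age models within age bins on
    modulated tissue-amount maps, clusters the resulting slope profiles with
    k-means under silhouette model selection, pairs gray and white matter
    clusters by spatial adjacency, profiles the dominant fiber direction of
    white matter clusters from principal-direction eigenvalue maps, and runs
    site/resolution and image-contrast quality-control analyses. Includes a
    fully synthetic cohort generator with known ground truth so every stage
    is testable without access to restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    cluster,
    mclust,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
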