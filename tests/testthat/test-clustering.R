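test_that("k-means recovers a separable partition and is deterministic", {
  set.seed(1)
  X <- rbind(matrix(rnorm(40, mean = 0, sd = 0.05), 10, 4),
             matrix(rnorm(40, mean = 1, sd = 0.05), 10, 4))
  sol <- kmeans_cluster(X, 2, restarts = 10, seed = 3)
  expect_equal(length(unique(sol$labels[1:10])), 1L)
  expect_equal(length(unique(sol$labels[11:20])), 1L)
  expect_false(sol$labels[1] == sol$labels[11])
  expect_identical(sol$labels,
                   kmeans_cluster(X, 2, restarts = 10, seed = 3)$labels)
  # centroids are the means of their members
  for (c in 1:2)
    expect_equal(unname(sol$centroids[c, ]),
                 unname(colMeans(X[sol$labels == c, ])), tolerance = 1e-12)
  expect_error(kmeans_cluster(X, 25), "exceeds")
  expect_error(kmeans_cluster(X, 1), "at least 2")
})

test_that("small-instance solutions attain the exhaustive-partition optimum", {
  for (s in 1:8) {
    set.seed(200 + s)
    X <- matrix(rnorm(24), 6, 4)
    got <- kmeans_cluster(X, 2, restarts = 10, seed = s)$tot_withinss
    expect_equal(got, brute_kmeans_wss(X), tolerance = 1e-10)
  }
})

test_that("the returned objective is no worse than cross-checks", {
  set.seed(5)
  # structured data: both implementations reach the same optimum
  X <- matrix(rnorm(200 * 4, sd = 0.1), 200, 4) +
    diag(4)[rep(1:4, each = 50), ]
  multi <- kmeans_cluster(X, 4, restarts = 10, seed = 7)
  single <- kmeans_cluster(X, 4, restarts = 1, seed = 7)
  expect_lte(multi$tot_withinss, single$tot_withinss + 1e-12)
  ref <- stats::kmeans(X, 4, nstart = 25, iter.max = 100)
  expect_equal(multi$tot_withinss, ref$tot.withinss, tolerance = 1e-8)
})

test_that("silhouette is exact for perfect separation and scans recover k", {
  # zero-noise two-profile matrix: mean silhouette is exactly 1
  X <- rbind(matrix(rep(c(1, 0, 0, 0), each = 5), 5),
             matrix(rep(c(0, 1, 0, 0), each = 5), 5))
  sol <- kmeans_cluster(X, 2, seed = 1)
  expect_equal(mean_silhouette(sol$labels, X), 1.0)

  profiles <- matrix(c(0, 0, 0, 0,
                       1, 0, 0, 0,
                       0, 1, 0, 0,
                       0, 0, 1, 0) * 0.1, 4, 4, byrow = TRUE)
  make_beta <- function(k) {
    set.seed(11)
    do.call(rbind, lapply(seq_len(k), function(i)
      matrix(rnorm(60 * 4, sd = 0.01), 60, 4) +
        rep(profiles[i, ], each = 60)))
  }
  scan4 <- silhouette_scan(make_beta(4), k_range = 2:6, restarts = 5,
                           seed = 2)
  expect_equal(scan4$best_k, 4L)
  # merging one profile away moves the peak accordingly
  scan3 <- silhouette_scan(make_beta(3), k_range = 2:6, restarts = 5,
                           seed = 2)
  expect_equal(scan3$best_k, 3L)

  expect_error(silhouette_scan(matrix(1, 30, 4), k_range = 2:5),
               "identical")
  expect_error(silhouette_scan(make_beta(2)[1:5, ], k_range = 2:10),
               "more rows")
})

test_that("cluster summaries match hand arithmetic", {
  X <- matrix(c(1, 2,
                3, 4,
                5, 6,
                7, 8,
                100, 200), 5, 2, byrow = TRUE)
  sol <- list(k = 2L, labels = c(1L, 1L, 1L, 1L, 2L))
  class(sol) <- "cluster_solution"
  s <- cluster_slope_summary(sol, X)
  expect_equal(s$mean_slope[s$cluster == 1], c(4, 5))
  expect_equal(s$sd_slope[s$cluster == 1],
               rep(sd(c(1, 3, 5, 7)), 2))
  # one-member cluster has zero SD
  expect_equal(s$sd_slope[s$cluster == 2], c(0, 0))
  expect_equal(s$n_voxels, c(4, 4, 1, 1))
})

test_that("trajectories integrate slopes piecewise-linearly", {
  edges <- c(4, 8, 10.5, 13.5, 18.5)
  flat <- trajectory_from_slopes(rep(0, 4), edges, anchor = 2)
  expect_equal(flat$knot_values, rep(2, 5))
  up <- trajectory_from_slopes(rep(1, 4), edges, anchor = 1)
  expect_equal(up$knot_values[5], 1 + 14.5)
  mixed <- trajectory_from_slopes(c(0.5, -1, 2, -0.25), edges, anchor = 3)
  expect_equal(mixed$knot_values,
               3 + cumsum(c(0, 0.5 * 4, -1 * 2.5, 2 * 3, -0.25 * 5)))
  # evaluation interpolates exactly inside a bin
  expect_equal(trajectory_value(mixed, 9.25),
               mixed$knot_values[2] - 1 * 1.25)
  expect_error(trajectory_from_slopes(rep(0, 4), edges, anchor = -1))
})
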