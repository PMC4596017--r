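test_that("mask rule is strict and guarantees disjointness", {
  gm <- array(c(0.6, 0.5, 0.3, 0.45), c(4, 1, 1))
  wm <- array(c(0.1, 0.5, 0.6, 0.42), c(4, 1, 1))
  m <- build_masks(gm, wm, 0.4)
  expect_equal(as.vector(m$gm), c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(as.vector(m$wm), c(FALSE, FALSE, TRUE, FALSE))
  # exact tie at 0.5 belongs to neither mask
  expect_false(m$gm[2, 1, 1] || m$wm[2, 1, 1])
  expect_false(any(m$gm & m$wm))
  expect_error(build_masks(gm * 0, wm, 0.4), "empty")
})

test_that("masks recover the generative supports", {
  atlas <- generate_atlas(seed = 2)
  coh <- generate_cohort(4, n_sites = 2, seed = 1)
  # unsmoothed noiseless maps: masks equal supports exactly
  maps <- simulate_cohort_maps(coh, atlas,
                               list(noise_sd = 0, fwhm = 0,
                                    gender_offset = 0, site_amplitude = 0,
                                    resolution_coef = 0),
                               seed = 1, n_sites = 2)
  m <- build_masks(mean_map(maps$gm, atlas$grid),
                   mean_map(maps$wm, atlas$grid), 0.4)
  expect_identical(as.vector(m$gm), as.vector(atlas$gm_labels > 0))
  expect_identical(as.vector(m$wm), as.vector(atlas$wm_labels > 0))

  # smoothed maps: masks stay inside a one-voxel dilation of the support
  maps_s <- simulate_cohort_maps(coh, atlas,
                                 list(noise_sd = 0, gender_offset = 0,
                                      site_amplitude = 0,
                                      resolution_coef = 0),
                                 seed = 1, n_sites = 2)
  ms <- build_masks(mean_map(maps_s$gm, atlas$grid),
                    mean_map(maps_s$wm, atlas$grid), 0.4)
  expect_false(any(ms$gm & ms$wm))
  expect_true(all(atlas$gm_labels[ms$gm] >= 0))
  # most masked voxels lie on the true support
  expect_gt(mean(atlas$gm_labels[ms$gm] > 0), 0.95)
  expect_gt(mean(atlas$wm_labels[ms$wm] > 0), 0.95)
})

test_that("total volume sums masked voxels times voxel volume", {
  mask <- array(c(TRUE, TRUE, FALSE, TRUE), c(4, 1, 1))
  ones <- array(1, c(4, 1, 1))
  expect_equal(total_volume(ones, mask, 1), 3)
  expect_equal(total_volume(ones * 2, mask, 1), 6)
  expect_equal(total_volume(ones, mask, 4), 3 * 64)
})

test_that("outlier distances follow the closed-form mean-shift account", {
  V <- 50; n <- 6; mvox <- 10; delta <- 0.3
  base <- array(runif(V), c(V, 1, 1))
  maps <- matrix(rep(as.vector(base), n), n, byrow = TRUE)
  mask <- array(TRUE, c(V, 1, 1))
  o0 <- detect_outliers(maps, mask)
  expect_equal(o0$distance, rep(0, n))
  expect_false(any(o0$flagged))

  maps[1, seq_len(mvox)] <- maps[1, seq_len(mvox)] + delta
  o <- detect_outliers(maps, mask)
  expect_equal(o$distance[1], mvox * delta^2 * ((n - 1) / n)^2,
               tolerance = 1e-10)
  expect_equal(o$distance[-1], rep(mvox * (delta / n)^2, n - 1),
               tolerance = 1e-10)
  expect_true(o$flagged[1])
  expect_false(any(o$flagged[-1]))
  expect_error(detect_outliers(maps[1:2, ], mask), "at least 3")
})

test_that("a clean homogeneous bin at default noise produces no flags", {
  atlas <- generate_atlas(seed = 6)
  coh <- generate_cohort(20, n_sites = 2, seed = 3)
  bin1 <- coh[coh$age_bin == 1, ]
  bin1$resolution <- 1   # homogeneous acquisition
  maps <- simulate_cohort_maps(bin1, atlas,
                               list(gender_offset = 0, site_amplitude = 0,
                                    resolution_coef = 0),
                               seed = 4, n_sites = 2)
  mask <- array(atlas$wm_labels > 0, atlas$grid)
  o <- detect_outliers(maps$wm, mask)
  expect_false(any(o$flagged))
})
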