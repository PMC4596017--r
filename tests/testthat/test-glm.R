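test_that("voxelwise OLS matches the lm() reference fit per voxel", {
  rec <- toy_records(n = 12, seed = 1, n_sites = 2)
  set.seed(2)
  Y <- matrix(rnorm(12 * 3), 12, 3)
  mask <- array(TRUE, c(3, 1, 1))
  fit <- fit_bin_glm(Y, rec, mask)
  for (v in 1:3) {
    df <- data.frame(y = Y[, v], gender = rec$gender, site = rec$site,
                     res = rec$resolution,
                     age_c = rec$age - mean(rec$age))
    ref <- stats::lm(y ~ gender + site + res + age_c, df)
    expect_equal(unname(fit$slope[v]), unname(coef(ref)["age_c"]),
                 tolerance = 1e-10)
    expect_equal(unname(fit$resvar[v]), summary(ref)$sigma^2,
                 tolerance = 1e-10)
  }
  expect_equal(fit$df_residual, 12 - 5)
})

test_that("design construction centers age and rejects collinearity", {
  rec <- toy_records(n = 10, n_sites = 2)
  X <- build_design(rec)
  expect_equal(sum(X[, "age"]), 0, tolerance = 1e-12)
  expect_true(all(rowSums(X[, grep("^site:", colnames(X))]) == 1))
  rec$gender <- "F"   # constant gender column
  expect_error(build_design(rec), "genderM")
  rec2 <- toy_records(n = 10, n_sites = 2)
  expect_error(fit_bin_glm(matrix(0, 9, 2), rec2,
                           array(TRUE, c(2, 1, 1))), "does not match")
})

test_that("noiseless unsmoothed data return exact per-voxel slopes", {
  atlas <- generate_atlas(grid = c(16, 16, 16), seed = 8)
  coh <- generate_cohort(12, n_sites = 3, seed = 5)
  maps <- simulate_cohort_maps(coh, atlas, list(noise_sd = 0, fwhm = 0),
                               seed = 1, n_sites = 3)
  mask <- array(atlas$gm_labels > 0, atlas$grid)
  for (b in c(1L, 3L)) {
    in_bin <- coh$age_bin == b
    fit <- fit_bin_glm(maps$gm[in_bin, , drop = FALSE], coh[in_bin, ], mask)
    truth <- atlas$slope_fields$gm[[b]][mask]
    expect_lt(max(abs(fit$slope - truth)), 1e-8)
  }
})

test_that("beta matrices index masked voxels exactly and round-trip", {
  atlas <- generate_atlas(grid = c(16, 16, 16), seed = 8)
  coh <- generate_cohort(12, n_sites = 3, seed = 5)
  maps <- simulate_cohort_maps(coh, atlas, list(noise_sd = 0.01, fwhm = 0),
                               seed = 1, n_sites = 3)
  mask <- array(atlas$wm_labels > 0, atlas$grid)
  fits <- lapply(1:4, function(b) {
    in_bin <- coh$age_bin == b
    fit_bin_glm(maps$wm[in_bin, , drop = FALSE], coh[in_bin, ], mask)
  })
  bm <- age_beta_matrix(fits)
  expect_equal(dim(bm$beta), c(sum(mask), 4L))
  # round trip matrix -> lattice -> matrix
  for (b in 1:4) {
    lat <- beta_to_lattice(bm, b)
    expect_equal(lat[bm$voxel_index], unname(bm$beta[, b]))
    expect_equal(unname(lat[mask]), unname(fits[[b]]$slope))
  }
  # a known voxel's row equals the slopes read from the lattices
  vox <- bm$voxel_index[17]
  expect_equal(unname(bm$beta[17, ]),
               vapply(fits, function(f) f$slope_map[vox], numeric(1)))
  expect_error(age_beta_matrix(fits[1:3]), "expected 4")
})

test_that("partial F statistics equal the explicit RSS-ratio oracle", {
  rec <- toy_records(n = 18, seed = 3, n_sites = 3)
  set.seed(4)
  y <- rnorm(18)
  mask <- array(TRUE, c(1, 1, 1))
  X_full <- build_design(rec)
  site_cols <- grep("^site:", colnames(X_full))
  for (effect in c("site", "resolution")) {
    fc <- f_contrast(matrix(y, ncol = 1), rec, mask, effect)
    X_red <- if (effect == "site")
      cbind(1, X_full[, -site_cols]) else
        X_full[, colnames(X_full) != "resolution"]
    expect_equal(fc$f_map[1, 1, 1], partial_f_oracle(y, X_full, X_red),
                 tolerance = 1e-10)
    # and the stats::anova reference agrees
    df <- data.frame(y = y, gender = rec$gender, site = rec$site,
                     res = rec$resolution, age = rec$age)
    full <- stats::lm(y ~ gender + site + res + age, df)
    red <- if (effect == "site") stats::lm(y ~ gender + res + age, df)
    else stats::lm(y ~ gender + site + age, df)
    ref <- stats::anova(red, full)
    expect_equal(fc$f_map[1, 1, 1], ref$F[2], tolerance = 1e-10)
    expect_equal(fc$p_map[1, 1, 1], ref$`Pr(>F)`[2], tolerance = 1e-10)
    expect_equal(fc$df1, ref$Df[2])
  }
})

test_that("site F-contrast lights up the region carrying the site effect", {
  atlas <- generate_atlas(grid = c(16, 16, 16), seed = 10)
  coh <- generate_cohort(24, n_sites = 3, seed = 6)
  effects <- list(noise_sd = 0.02, fwhm = 0, site_amplitude = 0.05,
                  site_sensitive_wm = 1L, site_sensitive_gm = 1L)
  maps <- simulate_cohort_maps(coh, atlas, effects, seed = 2, n_sites = 3)
  mask <- array(atlas$wm_labels > 0, atlas$grid)
  fc <- f_contrast(maps$wm, coh, mask, "site", alpha = 0.001)
  in_region <- atlas$wm_labels[mask] == 1L
  p <- fc$p_map[mask]
  expect_gt(mean(p[in_region] < 0.001), 0.99)
  expect_lt(mean(p[!in_region] < 0.001), 0.02)
})

test_that("proportional scaling removes global scale; ancova matches the oracle", {
  # subject maps differing only by an age-correlated global scale
  V <- 40; n <- 16
  rec <- toy_records(n = n, seed = 7, n_sites = 2)
  base <- runif(V, 0.5, 1)
  scale <- 1 + 0.05 * (rec$age - mean(rec$age))
  maps <- outer(scale, base)
  mask <- array(TRUE, c(V, 1, 1))
  rec$age_bin <- 1L
  prop <- fit_with_volume_adjustment(maps, rec, mask, "proportional")
  expect_lt(max(abs(prop[[1]]$slope)), 1e-10)
  none <- fit_with_volume_adjustment(maps, rec, mask, "none")
  # without adjustment every slope is positive: scale grows with age
  expect_true(all(none[[1]]$slope > 0))

  # ancova toy equals explicit normal equations with the extra column
  set.seed(8)
  y <- rnorm(n); w <- runif(n, 1, 2)
  anc <- fit_with_volume_adjustment(cbind(y, w), rec,
                                    array(TRUE, c(2, 1, 1)), "ancova")
  tv <- y + w
  X <- cbind(build_design(rec), tv = tv - mean(tv))
  expect_equal(unname(anc[[1]]$slope[1]),
               ols_oracle(X, y)[which(colnames(X) == "age")],
               tolerance = 1e-10)
  expect_error(fit_with_volume_adjustment(maps * 0, rec, mask,
                                          "proportional"), "zero total")
})
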