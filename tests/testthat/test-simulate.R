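test_that("separable smoothing matches direct 3D convolution", {
  set.seed(42)
  vol <- array(rnorm(125), c(5, 5, 5))
  got <- gaussian_smooth(vol, fwhm = 8, voxel_size = 4)
  want <- smooth3d_oracle(vol, fwhm = 8, voxel_size = 4)
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("zero-width smoothing is the identity", {
  vol <- array(runif(64), c(4, 4, 4))
  expect_identical(gaussian_smooth(vol, 0, 4), vol)
})

test_that("noiseless subject maps reproduce the generative identities", {
  atlas <- generate_atlas(seed = 3, slope_jitter_sd = 0)
  effects0 <- list(gender_offset = 0, site_amplitude = 0,
                   resolution_coef = 0, noise_sd = 0, fwhm = 0)
  edges <- c(4, 8, 10.5, 13.5, 18.5)
  mids <- (edges[-5] + edges[-1]) / 2
  rec <- data.frame(subject_id = "s1", age = mids[2], gender = "F",
                    site = "site1", resolution = 1, age_bin = 2L)
  m <- simulate_subject_maps(rec, atlas, effects0, seed = 1)
  # at the bin midpoint age the map equals the region baselines
  expect_true(all(m$gm[atlas$gm_labels > 0] == atlas$baselines[["gm"]]))
  expect_true(all(m$wm[atlas$wm_labels == 2] == atlas$baselines[["wm"]]))
  expect_true(all(m$gm[atlas$gm_labels == 0] == 0))

  # two subjects differing only in age: difference is slope * delta-age
  rec2 <- rec; rec2$age <- rec$age + 1.5
  m2 <- simulate_subject_maps(rec2, atlas, effects0, seed = 1)
  in3 <- atlas$gm_labels == 3
  expect_equal(m2$gm[in3] - m$gm[in3],
               rep(atlas$slopes$gm[3, 2] * 1.5, sum(in3)),
               tolerance = 1e-12)
})

test_that("cohort map simulation is seed-deterministic and rejects bad noise", {
  atlas <- generate_atlas(grid = c(16, 16, 16), seed = 5)
  coh <- generate_cohort(4, n_sites = 2, seed = 2)
  a <- simulate_cohort_maps(coh, atlas, list(noise_sd = 0.02), seed = 9,
                            n_sites = 2)
  b <- simulate_cohort_maps(coh, atlas, list(noise_sd = 0.02), seed = 9,
                            n_sites = 2)
  expect_identical(a, b)
  expect_error(simulate_cohort_maps(coh, atlas, list(noise_sd = -1),
                                    seed = 9, n_sites = 2), "nonnegative")
})

test_that("eigenvalue maps honor the noiseless limit and bounds", {
  atlas <- generate_atlas(seed = 4)
  e <- simulate_eigenvalue_maps(atlas, dominance = 1, noise_sd = 0, seed = 1)
  for (r in 1:4) {
    idx <- atlas$wm_labels == r
    dom <- atlas$wm_direction[r]
    for (d in c("x", "y", "z")) {
      expect_true(all(e[[d]][idx] == as.numeric(d == dom)))
    }
  }
  en <- simulate_eigenvalue_maps(atlas, dominance = 0.8, noise_sd = 0.3,
                                 seed = 1)
  for (d in c("x", "y", "z"))
    expect_true(all(en[[d]] >= 0 & en[[d]] <= 1))
  expect_error(simulate_eigenvalue_maps(atlas, dominance = 0), "dominance")
})

test_that("lobe intensity tables follow the generative contrast model", {
  coh <- generate_cohort(90, seed = 1)
  tab <- simulate_lobe_intensities(coh, seed = 1)
  expect_equal(nrow(tab), 4 * nrow(coh))
  expect_true(all(table(tab$subject_id) == 4))

  # zero noise and offsets: the contrast formula inverts exactly
  tab0 <- simulate_lobe_intensities(coh, base_contrast = 0.25,
                                    site_amplitude = rep(0, 4),
                                    age_coef = rep(0, 4),
                                    gm_noise_sd = 0, contrast_noise_sd = 0,
                                    seed = 1)
  C <- (tab0$wm_intensity - tab0$gm_intensity) / tab0$gm_intensity
  expect_equal(C, rep(0.25, nrow(tab0)), tolerance = 1e-12)

  # nonzero site offsets, zero noise: per-site mean contrasts differ by
  # exactly the zero-sum offsets (closed form)
  amp <- 0.03
  tab_s <- simulate_lobe_intensities(coh, site_amplitude = c(amp, 0, 0, 0),
                                     age_coef = rep(0, 4),
                                     gm_noise_sd = 0, contrast_noise_sd = 0,
                                     n_sites = 6, seed = 1)
  fr <- tab_s[tab_s$lobe == "frontal", ]
  fr <- merge(fr, coh[, c("subject_id", "site")])
  Cs <- (fr$wm_intensity - fr$gm_intensity) / fr$gm_intensity
  got <- tapply(Cs, fr$site, mean)
  want <- amp * seq(-1, 1, length.out = 6)
  expect_equal(as.vector(got[paste0("site", 1:6)] - mean(got)), want,
               tolerance = 1e-10)

  expect_error(simulate_lobe_intensities(coh, base_contrast = -2,
                                         gm_noise_sd = 0,
                                         contrast_noise_sd = 0, seed = 1),
               "nonpositive")
})
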