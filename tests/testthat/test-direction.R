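make_eig <- function(labels, triples) {
  # triples: list keyed by cluster id -> c(x, y, z)
  base <- array(0, dim(labels))
  eig <- list(x = base, y = base, z = base)
  for (c in names(triples)) {
    idx <- labels == as.integer(c)
    eig$x[idx] <- triples[[c]][1]
    eig$y[idx] <- triples[[c]][2]
    eig$z[idx] <- triples[[c]][3]
  }
  eig
}

test_that("pure-direction clusters yield unit proportions", {
  labels <- array(0L, c(4, 4, 4))
  labels[1:2, , ] <- 1L; labels[3:4, , ] <- 2L
  eig <- make_eig(labels, list(`1` = c(0.9, 0.05, 0.05),
                               `2` = c(0.05, 0.9, 0.05)))
  prof <- dominant_direction_profile(labels, eig, 0.4)
  expect_equal(prof$prop_x, c(1, 0))
  expect_equal(prof$prop_y, c(0, 1))
  expect_equal(prof$retained_fraction, c(1, 1))
  expect_equal(prof$count_x[1] + prof$count_y[1] + prof$count_z[1],
               prof$n_retained[1])
})

test_that("sub-threshold clusters are flagged undefined, not zeroed", {
  labels <- array(1L, c(2, 2, 2))
  eig <- make_eig(labels, list(`1` = c(0.3, 0.2, 0.1)))
  expect_warning(prof <- dominant_direction_profile(labels, eig, 0.4),
                 "undefined")
  expect_true(prof$undefined[1])
  expect_true(is.na(prof$prop_x[1]))
})

test_that("argmax ties break toward x then y and are tallied", {
  labels <- array(1L, c(2, 1, 1))
  eig <- make_eig(labels, list(`1` = c(0.5, 0.5, 0.2)))
  prof <- dominant_direction_profile(labels, eig, 0.4)
  expect_equal(prof$prop_x[1], 1)
  expect_equal(prof$n_ties[1], 2L)
})

test_that("raising the threshold never increases retention", {
  atlas <- generate_atlas(seed = 12)
  eig <- simulate_eigenvalue_maps(atlas, 0.7, 0.1, seed = 2)
  labels <- atlas$wm_labels
  prev <- rep(Inf, 4)
  for (thr in c(0.2, 0.4, 0.6, 0.8)) {
    prof <- suppressWarnings(dominant_direction_profile(labels, eig, thr))
    expect_true(all(prof$n_retained <= prev | is.na(prof$n_retained)))
    prev <- ifelse(is.na(prof$n_retained), 0, prof$n_retained)
  }
})

test_that("noiseless synthetic maps reproduce the assigned directions", {
  for (seed in 1:3) {
    atlas <- generate_atlas(seed = seed)
    eig <- simulate_eigenvalue_maps(atlas, dominance = 0.8, noise_sd = 0,
                                    seed = seed)
    prof <- dominant_direction_profile(atlas$wm_labels, eig, 0.4)
    for (r in 1:4) {
      want <- paste0("prop_", atlas$wm_direction[r])
      expect_equal(prof[[want]][r], 1)
    }
  }
})

test_that("sorted eigen matrices group by direction and sort by maximum", {
  labels <- array(1L, c(3, 1, 1))
  eig <- list(x = array(c(0.9, 0.1, 0.1), c(3, 1, 1)),
              y = array(c(0.05, 0.8, 0.1), c(3, 1, 1)),
              z = array(c(0.05, 0.1, 0.7), c(3, 1, 1)))
  sm <- sorted_eigen_matrix(labels, eig, 0.4, 1)
  expect_equal(sm$direction, c("x", "y", "z"))
  expect_equal(unname(sm$values[, "x"]), c(0.9, 0.1, 0.1))

  atlas <- generate_atlas(seed = 9)
  eigr <- simulate_eigenvalue_maps(atlas, 0.8, 0.05, seed = 3)
  smr <- sorted_eigen_matrix(atlas$wm_labels, eigr, 0.4, 2)
  mx <- apply(smr$values, 1, max)
  for (d in unique(smr$direction)) {
    grp <- mx[smr$direction == d]
    expect_true(all(diff(grp) <= 1e-12))
  }
  # duplicate rows keep a stable coordinate order
  labels2 <- array(1L, c(4, 1, 1))
  eig2 <- list(x = array(0.9, c(4, 1, 1)), y = array(0.1, c(4, 1, 1)),
               z = array(0.1, c(4, 1, 1)))
  sm2 <- sorted_eigen_matrix(labels2, eig2, 0.4, 1)
  expect_equal(sm2$voxel_index, 1:4)
})
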