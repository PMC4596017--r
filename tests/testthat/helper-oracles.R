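# Independent oracles used across test files. These deliberately avoid the
# package's own code paths: plain normal equations, exhaustive search, and
# direct triple-loop convolution.

# OLS coefficients by explicit normal equations
ols_oracle <- function(X, y) {
  as.vector(solve(t(X) %*% X, t(X) %*% y))
}

# residual sum of squares of an OLS fit, via the oracle coefficients
rss_oracle <- function(X, y) {
  sum((y - X %*% solve(t(X) %*% X, t(X) %*% y))^2)
}

# partial F by explicit RSS ratio
partial_f_oracle <- function(y, X_full, X_reduced) {
  rss_f <- rss_oracle(X_full, y)
  rss_r <- rss_oracle(X_reduced, y)
  df1 <- ncol(X_full) - ncol(X_reduced)
  df2 <- length(y) - ncol(X_full)
  ((rss_r - rss_f) / df1) / (rss_f / df2)
}

# exhaustive minimum within-cluster sum of squares over all 2-cluster
# labelings of the rows of X
brute_kmeans_wss <- function(X, k = 2) {
  m <- nrow(X)
  stopifnot(k == 2, m <= 12)
  best <- Inf
  for (code in 0:(2^m - 1)) {
    lab <- as.integer(intToBits(code))[1:m] + 1L
    if (length(unique(lab)) < k) next
    w <- 0
    for (c in seq_len(k)) {
      r <- X[lab == c, , drop = FALSE]
      w <- w + sum(sweep(r, 2, colMeans(r))^2)
    }
    if (w < best) best <- w
  }
  best
}

# direct (non-separable) 3D Gaussian convolution with zero padding
smooth3d_oracle <- function(vol, fwhm, voxel_size) {
  sigma <- fwhm / (2 * sqrt(2 * log(2))) / voxel_size
  r <- max(1L, ceiling(4 * sigma))
  k1 <- exp(-((-r):r)^2 / (2 * sigma^2))
  k1 <- k1 / sum(k1)
  K <- outer(outer(k1, k1), k1)   # (2r+1)^3 kernel
  d <- dim(vol)
  out <- array(0, d)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    acc <- 0
    for (dx in -r:r) for (dy in -r:r) for (dz in -r:r) {
      sx <- x + dx; sy <- y + dy; sz <- z + dz
      if (sx >= 1 && sx <= d[1] && sy >= 1 && sy <= d[2] &&
          sz >= 1 && sz <= d[3])
        acc <- acc + vol[sx, sy, sz] * K[dx + r + 1, dy + r + 1, dz + r + 1]
    }
    out[x, y, z] <- acc
  }
  out
}

# map each recovered cluster to the ground-truth region holding most of
# its voxels
majority_region <- function(labels_map, truth_map, mask, k) {
  lab <- labels_map[mask]
  tr <- truth_map[mask]
  vapply(seq_len(k), function(c) {
    tb <- table(tr[lab == c])
    as.integer(names(which.max(tb)))
  }, integer(1))
}

# a small cohort-like record table; factors are shuffled independently so
# the design stays full rank (verified for the seeds used in the tests)
toy_records <- function(n = 12, seed = 1, n_sites = 2, bin = 1L) {
  set.seed(seed)
  data.frame(
    subject_id = sprintf("t%02d", seq_len(n)),
    age = runif(n, 4, 8),
    gender = sample(rep_len(c("M", "F"), n)),
    site = sample(rep_len(paste0("site", seq_len(n_sites)), n)),
    resolution = sample(c(1, 1.5, 3), n, replace = TRUE),
    age_bin = bin,
    stringsAsFactors = FALSE)
}
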