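#' Build the voxelwise design matrix
#'
#' Columns: mean-centered age, a male indicator, one indicator per site
#' present in the sample (cell-means coding, no separate intercept — the
#' site block spans the intercept), linear resolution (mean-centered by
#' default), and optionally a mean-centered total tissue volume column.
#'
#' @param records Participant data.frame (one row per subject, in map
#'   order).
#' @param center_resolution Mean-center the resolution column (slopes are
#'   invariant to this; default TRUE).
#' @param total_volume Optional numeric vector of per-subject total
#'   tissue volume to append as a nuisance column.
#' @param covariates Which nuisance covariates to include besides age
#'   (default all of gender, site, resolution). When `"site"` is
#'   excluded, a plain intercept column replaces the site block.
#' @return Numeric design matrix with named columns; rank-deficiency is
#'   an error naming the collinear columns.
#' @export
build_design <- function(records, center_resolution = TRUE,
                         total_volume = NULL,
                         covariates = c("gender", "site", "resolution")) {
  n <- nrow(records)
  age <- records$age - mean(records$age)
  X <- cbind(age = age)
  if ("site" %in% covariates) {
    site_levels <- sort(unique(records$site))
    S <- outer(records$site, site_levels, "==") * 1
    colnames(S) <- paste0("site:", site_levels)
    X <- cbind(X, S)
  } else {
    X <- cbind(X, intercept = 1)
  }
  if ("gender" %in% covariates)
    X <- cbind(X, genderM = as.numeric(records$gender == "M"))
  if ("resolution" %in% covariates) {
    res <- records$resolution
    if (center_resolution) res <- res - mean(res)
    X <- cbind(X, resolution = res)
  }
  if (!is.null(total_volume)) {
    stopifnot(length(total_volume) == n)
    X <- cbind(X, total_volume = total_volume - mean(total_volume))
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  X
}

# OLS of Y (n x m) on X; returns coefficients, residual matrix, rank
ols_fit <- function(X, Y) {
  fit <- lm.fit(X, Y)
  coefs <- fit$coefficients
  if (is.null(dim(coefs))) coefs <- matrix(coefs, ncol = 1L,
                                           dimnames = list(names(coefs)))
  res <- fit$residuals
  if (is.null(dim(res))) res <- matrix(res, ncol = 1L)
  list(coefficients = coefs, residuals = res, rank = fit$rank)
}

#' Fit the per-bin voxelwise age model
#'
#' At every masked voxel, ordinary least squares of tissue amount on
#' mean-centered age, gender, site (one indicator per site), and linear
#' resolution. Returns the age coefficient (tissue amount per year) and
#' the unbiased residual variance per voxel. Voxel-level significance of
#' the age effect is deliberately not computed: the slopes themselves are
#' the object of the downstream clustering.
#'
#' @param maps Subject-by-voxel matrix (or list of 3D arrays) for the
#'   subjects of one bin, rows in `records` order.
#' @param records Participant table for the same subjects.
#' @param mask Logical lattice.
#' @param center_resolution Passed to [build_design()].
#' @param total_volume Optional per-subject total volume nuisance column.
#' @param covariates Passed to [build_design()].
#' @return Object of class `bin_glm_fit`: list with `slope` and `resvar`
#'   (masked vectors), `coefficients` (p x voxels), `slope_map` and
#'   `resvar_map` lattices, `df_residual`, `mask`.
#' @export
fit_bin_glm <- function(maps, records, mask, center_resolution = TRUE,
                        total_volume = NULL,
                        covariates = c("gender", "site", "resolution")) {
  maps <- as_map_matrix(maps)
  if (nrow(maps) != nrow(records))
    stop("number of maps (", nrow(maps), ") does not match number of ",
         "participant records (", nrow(records), ")")
  X <- build_design(records, center_resolution, total_volume, covariates)
  Y <- maps[, as.vector(mask), drop = FALSE]
  fit <- ols_fit(X, Y)
  df_residual <- nrow(X) - fit$rank
  resvar <- colSums(fit$residuals^2) / df_residual
  slope <- fit$coefficients["age", ]
  structure(list(slope = slope, resvar = resvar,
                 coefficients = fit$coefficients,
                 slope_map = embed_in_lattice(slope, mask),
                 resvar_map = embed_in_lattice(resvar, mask),
                 df_residual = df_residual, mask = mask),
            class = "bin_glm_fit")
}

#' Assemble the voxel-by-bin age-slope matrix
#'
#' Rows are masked voxels in lexicographic (column-major) lattice order;
#' columns are age bins in ascending order. The stored voxel index allows
#' an exact inverse mapping back to lattice coordinates.
#'
#' @param fits List of `bin_glm_fit` objects, one per bin, ascending,
#'   all fitted on the same mask.
#' @param n_bins_expected Expected bin count (default 4); pass a
#'   different value to override.
#' @return Object of class `beta_matrix`: list with `beta` (voxels x
#'   bins), `voxel_index` (linear lattice indices), `grid`.
#' @export
age_beta_matrix <- function(fits, n_bins_expected = 4L) {
  if (length(fits) != n_bins_expected)
    stop("expected ", n_bins_expected, " per-bin fits, got ", length(fits))
  mask <- fits[[1]]$mask
  for (f in fits) stopifnot(identical(f$mask, mask))
  beta <- do.call(cbind, lapply(fits, `[[`, "slope"))
  colnames(beta) <- paste0("bin", seq_along(fits))
  structure(list(beta = beta, voxel_index = which(as.vector(mask)),
                 grid = dim(mask)),
            class = "beta_matrix")
}

#' Map one column of a beta matrix back onto the lattice
#'
#' @param bm A `beta_matrix`.
#' @param bin Bin column to embed.
#' @return 3D array (NA outside the mask).
#' @export
beta_to_lattice <- function(bm, bin = 1L) {
  arr <- array(NA_real_, bm$grid)
  arr[bm$voxel_index] <- bm$beta[, bin]
  arr
}

# Partial F test comparing nested OLS fits, vectorized over columns of Y.
partial_f <- function(Y, X_full, X_reduced) {
  ff <- ols_fit(X_full, Y)
  fr <- ols_fit(X_reduced, Y)
  rss_f <- colSums(ff$residuals^2)
  rss_r <- colSums(fr$residuals^2)
  df1 <- ff$rank - fr$rank
  df2 <- nrow(Y) - ff$rank
  if (df1 < 1L) stop("reduced model is not nested with fewer parameters")
  F <- ((rss_r - rss_f) / df1) / (rss_f / df2)
  list(F = F, df1 = df1, df2 = df2,
       p = pf(F, df1, df2, lower.tail = FALSE))
}

#' Voxelwise F-contrast for site or resolution
#'
#' Fits the full-sample model (mean-centered age, gender, one indicator
#' per site, linear resolution) and compares it against the model with
#' the tested effect removed: for `site` the site block is replaced by a
#' plain intercept (a multi-column, "nonlinear" contrast); for
#' `resolution` the single resolution column is dropped. Voxels with
#' p below `alpha` (uncorrected) form the suprathreshold lattice.
#'
#' @param maps Full-sample subject-by-voxel matrix (or list of arrays).
#' @param records Full-sample participant table.
#' @param mask Logical lattice.
#' @param effect `"site"` or `"resolution"`.
#' @param alpha Uncorrected voxelwise threshold (default 0.001).
#' @return Object of class `contrast_result`: `f_map`, `p_map`,
#'   `suprathreshold` lattices, `df1`, `df2`, `effect`, `alpha`,
#'   `suprathreshold_fraction`.
#' @export
f_contrast <- function(maps, records, mask,
                       effect = c("site", "resolution"), alpha = 0.001) {
  effect <- match.arg(effect)
  maps <- as_map_matrix(maps)
  if (nrow(maps) != nrow(records)) stop("maps/records mismatch")
  X_full <- build_design(records)
  site_cols <- grep("^site:", colnames(X_full))
  if (effect == "site") {
    X_red <- cbind(intercept = 1,
                   X_full[, -site_cols, drop = FALSE])
  } else {
    X_red <- X_full[, colnames(X_full) != "resolution", drop = FALSE]
  }
  Y <- maps[, as.vector(mask), drop = FALSE]
  pf_res <- partial_f(Y, X_full, X_red)
  supra <- embed_in_lattice(pf_res$p < alpha, mask, fill = FALSE)
  structure(list(f_map = embed_in_lattice(pf_res$F, mask),
                 p_map = embed_in_lattice(pf_res$p, mask),
                 suprathreshold = supra,
                 df1 = pf_res$df1, df2 = pf_res$df2,
                 effect = effect, alpha = alpha,
                 suprathreshold_fraction = mean(pf_res$p < alpha)),
            class = "contrast_result")
}

#' Per-bin age slopes under total-volume adjustment
#'
#' `mode = "none"` fits the main model in each bin. `"proportional"`
#' divides each subject's map by its total tissue volume, rescaled by the
#' bin-sample mean total so values keep tissue-amount units, before
#' fitting. `"ancova"` appends mean-centered total tissue volume as a
#' nuisance design column.
#'
#' @param maps Subject-by-voxel matrix for the whole cohort.
#' @param records Full cohort participant table (column `age_bin`).
#' @param mask Logical lattice.
#' @param mode Adjustment mode.
#' @param voxel_size Voxel size in mm for the total-volume computation.
#' @return List of `bin_glm_fit` objects (ascending bins) with the mode
#'   attached as attribute `mode`.
#' @export
fit_with_volume_adjustment <- function(maps, records, mask,
                                       mode = c("none", "proportional",
                                                "ancova"),
                                       voxel_size = 1) {
  mode <- match.arg(mode)
  maps <- as_map_matrix(maps)
  mvec <- as.vector(mask)
  tv <- rowSums(maps[, mvec, drop = FALSE]) * voxel_size^3
  if (mode != "none" && any(tv == 0))
    stop("zero total tissue volume for subject(s): ",
         paste(which(tv == 0), collapse = ", "))
  bins <- sort(unique(records$age_bin))
  fits <- vector("list", length(bins))
  for (i in seq_along(bins)) {
    in_bin <- records$age_bin == bins[i]
    Yb <- maps[in_bin, , drop = FALSE]
    rb <- records[in_bin, , drop = FALSE]
    tvb <- tv[in_bin]
    if (mode == "proportional") {
      Yb <- Yb * (mean(tvb) / tvb)
      fits[[i]] <- fit_bin_glm(Yb, rb, mask)
    } else if (mode == "ancova") {
      fits[[i]] <- fit_bin_glm(Yb, rb, mask, total_volume = tvb)
    } else {
      fits[[i]] <- fit_bin_glm(Yb, rb, mask)
    }
  }
  attr(fits, "mode") <- mode
  fits
}
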