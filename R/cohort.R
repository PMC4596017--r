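#' Generate a synthetic study cohort
#'
#' Draws a balanced participant table: four age bins with `n_per_bin`
#' subjects each, exactly half male and half female per bin, sites assigned
#' round-robin (so each bin is balanced across sites) and then shuffled,
#' and isotropic acquisition resolution sampled with a higher probability
#' of coarse voxels in the youngest bin.
#'
#' Ages are drawn uniformly within each bin. Bins are half-open
#' `[lo, hi)` except the last, which is closed.
#'
#' @param n_per_bin Subjects per age bin (must be even; default 90).
#' @param bin_edges Five ascending ages in years defining four bins
#'   (default `c(4, 8, 10.5, 13.5, 18.5)`).
#' @param n_sites Number of acquisition sites (default 6, must be >= 2).
#' @param seed Integer seed; the same seed and arguments reproduce the
#'   table exactly.
#' @param resolutions Possible isotropic voxel sizes in mm.
#' @param res_probs_youngest,res_probs_older Sampling probabilities over
#'   `resolutions` for the youngest bin and for all other bins.
#' @return A data.frame with columns `subject_id`, `age`, `gender`
#'   (`"M"`/`"F"`), `site` (`"site1"`...), `resolution` (mm), `age_bin`
#'   (1..4).
#' @export
generate_cohort <- function(n_per_bin = 90L,
                            bin_edges = c(4, 8, 10.5, 13.5, 18.5),
                            n_sites = 6L,
                            seed = 1L,
                            resolutions = c(1.0, 1.5, 3.0),
                            res_probs_youngest = c(0.6, 0.2, 0.2),
                            res_probs_older = c(0.8, 0.15, 0.05)) {
  n_per_bin <- as.integer(n_per_bin)
  if (n_per_bin < 2L || n_per_bin %% 2L != 0L)
    stop("`n_per_bin` must be an even positive count, got ", n_per_bin)
  if (length(bin_edges) < 3L || any(diff(bin_edges) <= 0))
    stop("`bin_edges` must be strictly ascending")
  if (n_sites < 2L)
    stop("`n_sites` must be at least 2")
  stopifnot(length(res_probs_youngest) == length(resolutions),
            length(res_probs_older) == length(resolutions))

  n_bins <- length(bin_edges) - 1L
  sites <- paste0("site", seq_len(n_sites))

  set.seed(as.integer(seed))
  out <- vector("list", n_bins)
  for (b in seq_len(n_bins)) {
    lo <- bin_edges[b]; hi <- bin_edges[b + 1L]
    age <- runif(n_per_bin, lo, hi)
    gender <- sample(rep(c("M", "F"), each = n_per_bin %/% 2L))
    site <- sample(rep_len(sites, n_per_bin))
    probs <- if (b == 1L) res_probs_youngest else res_probs_older
    resolution <- sample(resolutions, n_per_bin, replace = TRUE, prob = probs)
    out[[b]] <- data.frame(age = age, gender = gender, site = site,
                           resolution = resolution, age_bin = b,
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  out <- cbind(subject_id = sprintf("sub-%03d", seq_len(nrow(out))), out)
  rownames(out) <- NULL
  out
}

#' Assign ages to bins
#'
#' Half-open `[lo, hi)` bins, last bin closed at the top.
#'
#' @param age Numeric ages in years.
#' @param bin_edges Ascending bin edges.
#' @return Integer bin index (NA outside the range).
#' @export
age_to_bin <- function(age, bin_edges = c(4, 8, 10.5, 13.5, 18.5)) {
  b <- findInterval(age, bin_edges, rightmost.closed = TRUE)
  b[b < 1L | b > length(bin_edges) - 1L] <- NA_integer_
  b
}
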