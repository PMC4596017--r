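# shift a 3D array by an integer offset, zero/FALSE-filling the border
shift_array <- function(a, off) {
  d <- dim(a)
  out <- array(if (is.logical(a)) FALSE else 0, d)
  src <- dst <- vector("list", 3L)
  for (i in 1:3) {
    if (off[i] >= 0) {
      src[[i]] <- seq_len(d[i] - off[i])
      dst[[i]] <- src[[i]] + off[i]
    } else {
      src[[i]] <- seq_len(d[i] + off[i]) - off[i]
      dst[[i]] <- seq_len(d[i] + off[i])
    }
    if (!length(src[[i]])) return(out)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <-
    a[src[[1]], src[[2]], src[[3]]]
  out
}

NEIGHBORS26 <- local({
  g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  g[rowSums(abs(g)) > 0, , drop = FALSE]
})

# one 26-connected binary dilation step, repeated `radius` times
dilate_mask <- function(mask, radius = 1L) {
  for (r in seq_len(radius)) {
    acc <- mask
    for (i in seq_len(nrow(NEIGHBORS26)))
      acc <- acc | shift_array(mask, NEIGHBORS26[i, ])
    mask <- acc
  }
  mask
}

# number of 26-adjacent voxel pairs (a in A, b in B)
contact_count <- function(A, B) {
  total <- 0
  for (i in seq_len(nrow(NEIGHBORS26)))
    total <- total + sum(A & shift_array(B, NEIGHBORS26[i, ]))
  total
}

# all permutations of 1..k in lexicographic order
permutations_of <- function(k) {
  if (k == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_of(k - 1L)
  out <- matrix(0L, 0L, k)
  for (first in seq_len(k)) {
    rest <- matrix(setdiff(seq_len(k), first)[sub], nrow(sub))
    out <- rbind(out, cbind(first, rest))
  }
  unname(out)
}

#' Pair gray and white matter clusters by spatial adjacency
#'
#' Operationalizes cluster pairing as a deterministic assignment problem:
#' each pair's adjacency score is the number of 26-neighborhood voxel
#' contacts between the two cluster masks after dilating each by
#' `dilate_radius`, and the returned bijection maximizes the total score
#' over all permutations (exhaustive search; ties resolved toward
#' lexicographic cluster order).
#'
#' @param gm_labels,wm_labels Integer label lattices (0 = background).
#' @param dilate_radius Dilation radius in voxels before scoring
#'   (default 1).
#' @param mode `"bijection"` (requires equal cluster counts) or
#'   `"best_match"` (each gray cluster keeps its best-scoring white
#'   cluster, not necessarily one-to-one).
#' @return Object of class `pairing_result`: `pairs` (data.frame
#'   `gm_cluster`, `wm_cluster`, `score`), `scores` (full matrix),
#'   `method`, and `uninformative` (TRUE when all scores are 0).
#' @export
pair_clusters <- function(gm_labels, wm_labels, dilate_radius = 1L,
                          mode = c("bijection", "best_match")) {
  mode <- match.arg(mode)
  stopifnot(identical(dim(gm_labels), dim(wm_labels)))
  k_gm <- max(gm_labels); k_wm <- max(wm_labels)
  if (mode == "bijection" && k_gm != k_wm)
    stop("cluster counts differ (", k_gm, " vs ", k_wm,
         "); use mode = \"best_match\" for a non-bijective pairing")
  gm_masks <- lapply(seq_len(k_gm),
                     function(c) dilate_mask(gm_labels == c, dilate_radius))
  wm_masks <- lapply(seq_len(k_wm),
                     function(c) dilate_mask(wm_labels == c, dilate_radius))
  scores <- matrix(0, k_gm, k_wm,
                   dimnames = list(paste0("gm", seq_len(k_gm)),
                                   paste0("wm", seq_len(k_wm))))
  for (g in seq_len(k_gm))
    for (w in seq_len(k_wm))
      scores[g, w] <- contact_count(gm_masks[[g]], wm_masks[[w]])

  if (mode == "bijection") {
    if (k_gm > 10L) stop("exhaustive pairing supports at most 10 clusters")
    perms <- permutations_of(k_gm)
    totals <- apply(perms, 1L,
                    function(p) sum(scores[cbind(seq_len(k_gm), p)]))
    assignment <- perms[which.max(totals), ]   # first max = lexicographic
  } else {
    assignment <- apply(scores, 1L, which.max)
  }
  pairs <- data.frame(gm_cluster = seq_len(k_gm),
                      wm_cluster = as.integer(assignment),
                      score = scores[cbind(seq_len(k_gm), assignment)])
  structure(list(pairs = pairs, scores = scores,
                 method = paste0("dilated-contact-count/", mode,
                                 "/r", dilate_radius),
                 uninformative = all(scores == 0)),
            class = "pairing_result")
}

# align labels of b to a: permutation of 1..k maximizing agreement
align_labels <- function(labels_a, labels_b, k) {
  overlap <- table(factor(labels_a, seq_len(k)),
                   factor(labels_b, seq_len(k)))
  if (k <= 8L) {
    perms <- permutations_of(k)
    agree <- apply(perms, 1L,
                   function(p) sum(overlap[cbind(seq_len(k), p)]))
    perms[which.max(agree), ]
  } else {
    # greedy fallback for large k
    perm <- integer(k)
    ov <- overlap
    for (i in seq_len(k)) {
      best <- arrayInd(which.max(ov), dim(ov))
      perm[best[1]] <- best[2]
      ov[best[1], ] <- -1; ov[, best[2]] <- -1
    }
    perm
  }
}

#' Compare two clustering solutions on the same voxel set
#'
#' Aligns cluster labels by the agreement-maximizing permutation, then
#' reports the adjusted Rand index, per-cluster Dice coefficients, and a
#' voxelwise agreement vector (optionally embedded as a lattice).
#'
#' @param a,b `cluster_solution` objects (or plain integer label
#'   vectors) over the same rows.
#' @param mask Optional logical lattice to embed the agreement map into.
#' @return List with `ari`, `dice` (per aligned pair), `alignment`
#'   (label of `b` matched to each label of `a`), `agreement` (logical
#'   per row), and `agreement_map` (lattice or NULL).
#' @export
compare_solutions <- function(a, b, mask = NULL) {
  la <- if (inherits(a, "cluster_solution")) a$labels else as.integer(a)
  lb <- if (inherits(b, "cluster_solution")) b$labels else as.integer(b)
  if (length(la) != length(lb))
    stop("solutions cover different numbers of voxels")
  ari <- mclust::adjustedRandIndex(la, lb)
  k <- max(la, lb)
  perm <- align_labels(la, lb, k)
  dice <- numeric(k)
  for (c in seq_len(k)) {
    A <- la == c; B <- lb == perm[c]
    dice[c] <- if (sum(A) + sum(B) == 0) NA_real_ else
      2 * sum(A & B) / (sum(A) + sum(B))
  }
  agreement <- lb == perm[la]
  agreement_map <- if (!is.null(mask))
    embed_in_lattice(agreement, mask, fill = NA) else NULL
  list(ari = ari, dice = dice, alignment = perm,
       agreement = agreement, agreement_map = agreement_map)
}
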