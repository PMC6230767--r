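# Mutual-information scoring of PPHMM features that discriminate two
# virus groups, with repeated small-sample subsampling.

#' Plug-in mutual information between a binary grouping and presence
#'
#' Scores are binarised at presence (score > 0) and the mutual
#' information of the 2x2 empirical joint distribution is returned in
#' bits, with the convention 0 * log 0 = 0. For binary/binary variables
#' the value lies in \[0, 1\] bits and is 0 exactly when the joint
#' factorises into its marginals.
#'
#' @param labels Binary vector (two distinct values at most).
#' @param scores Numeric vector of PPHMM scores, same length.
#' @param bins Number of score bins; the default 2 is the
#'   presence/absence estimator. Larger values quantile-bin the
#'   positive scores.
#' @return Mutual information in bits.
#' @export
mutual_information <- function(labels, scores, bins = 2) {
  if (length(labels) != length(scores)) stop("length mismatch")
  if (length(labels) < 2L) stop("need at least 2 observations")
  ul <- unique(labels)
  if (length(ul) > 2L) stop("labels must be binary")
  x <- match(labels, ul)
  y <- if (bins <= 2) {
    as.integer(scores > 0)
  } else {
    pos <- scores > 0
    qb <- rep(0L, length(scores))
    if (any(pos)) {
      brk <- unique(stats::quantile(scores[pos],
                                    probs = seq(0, 1, length.out = bins)))
      qb[pos] <- as.integer(cut(scores[pos], breaks = brk,
                                include.lowest = TRUE))
    }
    qb
  }
  joint <- table(x, y) / length(x)
  px <- rowSums(joint)
  py <- colSums(joint)
  mi <- 0
  for (i in seq_along(px)) {
    for (j in seq_along(py)) {
      p <- joint[i, j]
      if (p > 0) mi <- mi + p * log2(p / (px[i] * py[j]))
    }
  }
  max(0, mi)
}

#' Subsampled mean mutual information per PPHMM
#'
#' Measures how strongly each PPHMM feature discriminates two virus
#' groups. PPHMMs with zero scores across both groups are excluded. In
#' each replicate, `per_group` genomes are sampled uniformly without
#' replacement from each group and the plug-in MI between group
#' membership and feature presence is computed; the per-PPHMM mean (and
#' dispersion) over `reps` replicates is reported. Small per-group
#' samples make the estimator deliberately coarse, hence the averaging.
#'
#' @param table A `cgj_signature_table`.
#' @param group_a,group_b Disjoint genome-id vectors.
#' @param per_group Genomes sampled per group per replicate.
#' @param reps Number of replicates.
#' @param seed RNG seed.
#' @param bins Passed to [mutual_information()].
#' @return Data frame: `pphmm_id`, `mean_mi_bits`, `sd`, `n_reps`,
#'   `present_a`, `present_b` (presence counts over the full groups),
#'   ordered by decreasing mean MI.
#' @export
mean_mi_subsampled <- function(table, group_a, group_b, per_group = 2,
                               reps = 100, seed = 1, bins = 2) {
  if (length(intersect(group_a, group_b))) {
    stop("groups must be disjoint")
  }
  if (!all(c(group_a, group_b) %in% table$genome_ids)) {
    stop("unknown genome id in group definition")
  }
  if (length(group_a) < per_group || length(group_b) < per_group) {
    stop("per_group exceeds a group's size")
  }
  A <- table$pphmm_block[group_a, , drop = FALSE]
  B <- table$pphmm_block[group_b, , drop = FALSE]
  keep <- colSums(A > 0) + colSums(B > 0) > 0
  if (!any(keep)) {
    return(data.frame(pphmm_id = character(), mean_mi_bits = numeric(),
                      sd = numeric(), n_reps = integer(),
                      present_a = integer(), present_b = integer(),
                      stringsAsFactors = FALSE))
  }
  A <- A[, keep, drop = FALSE]
  B <- B[, keep, drop = FALSE]
  pids <- colnames(A)
  mi_mat <- matrix(0, reps, length(pids))
  with_rng_seed(seed, {
    for (r in seq_len(reps)) {
      ia <- sample.int(nrow(A), per_group)
      ib <- sample.int(nrow(B), per_group)
      lab <- rep(c(0L, 1L), each = per_group)
      sub <- rbind(A[ia, , drop = FALSE], B[ib, , drop = FALSE])
      mi_mat[r, ] <- vapply(seq_along(pids), function(k)
        mutual_information(lab, sub[, k], bins = bins), numeric(1))
    }
  })
  out <- data.frame(pphmm_id = pids,
                    mean_mi_bits = colMeans(mi_mat),
                    sd = apply(mi_mat, 2, stats::sd),
                    n_reps = reps,
                    present_a = colSums(A > 0),
                    present_b = colSums(B > 0),
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(-out$mean_mi_bits, out$pphmm_id), , drop = FALSE]
}
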