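# Composite generalized Jaccard (CGJ) similarity and distance.

#' Generalized Jaccard similarity of two non-negative vectors
#'
#' `sum(pmin(a, b)) / sum(pmax(a, b))`; two all-zero vectors score 0
#' (no shared evidence), not 1.
#'
#' @param a,b Equal-length non-negative numeric vectors.
#' @return Similarity in \[0, 1\].
#' @export
generalized_jaccard <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch")
  if (length(a) && (min(a) < 0 || min(b) < 0)) {
    stop("generalized Jaccard requires non-negative entries")
  }
  den <- sum(pmax(a, b))
  if (den == 0) return(0)
  sum(pmin(a, b)) / den
}

#' Composite generalized Jaccard similarity of two genomes
#'
#' Geometric mean of the generalized Jaccard scores of the pair's PPHMM
#' signatures and GOM signatures. When the table carries no GOM columns
#' the PPHMM Jaccard alone is returned.
#'
#' @param table A `cgj_signature_table`.
#' @param i,j Genome ids or row indices.
#' @return CGJ similarity in \[0, 1\].
#' @export
cgj_similarity <- function(table, i, j) {
  jp <- generalized_jaccard(table$pphmm_block[i, ], table$pphmm_block[j, ])
  if (ncol(table$gom_block) == 0L) return(jp)
  jg <- generalized_jaccard(table$gom_block[i, ], table$gom_block[j, ])
  sqrt(jp * jg)
}

#' Pairwise CGJ distance matrix
#'
#' `D[i, j] = 1 - CGJ(i, j)`, symmetric with a zero diagonal.
#'
#' @param table A `cgj_signature_table`.
#' @return Object of class `cgj_distance_matrix`: a labelled symmetric
#'   numeric matrix.
#' @export
distance_matrix <- function(table) {
  ids <- table$genome_ids
  n <- length(ids)
  if (n == 0L) stop("empty signature table")
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  pb <- table$pphmm_block
  gb <- table$gom_block
  has_gom <- ncol(gb) > 0L
  for (i in seq_len(n - 1L)) {
    ai <- pb[i, ]
    gi <- if (has_gom) gb[i, ] else NULL
    for (j in (i + 1L):n) {
      jp <- generalized_jaccard(ai, pb[j, ])
      s <- if (has_gom) sqrt(jp * generalized_jaccard(gi, gb[j, ])) else jp
      D[i, j] <- D[j, i] <- 1 - s
    }
  }
  structure(D, class = c("cgj_distance_matrix", "matrix", "array"))
}

#' Stratified CGJ distance distributions
#'
#' Splits the labelled pairwise distances at a taxonomic rank into the
#' within-rank and between-rank strata and bins each stratum at 0.02
#' intervals on \[0, 1\]. Pairs in which either genome lacks a label at
#' the rank are excluded.
#'
#' @param D A `cgj_distance_matrix`.
#' @param manifest The `cgj_manifest` carrying taxonomy.
#' @param rank `"family"` or `"genus"`.
#' @return List with elements `within` and `between`, each a list of
#'   `breaks` (bin edges), `counts`, `distances` (the raw stratum
#'   values) and `stratum` label.
#' @export
distance_distributions <- function(D, manifest, rank = c("family", "genus")) {
  rank <- match.arg(rank)
  ids <- rownames(D)
  labels <- vapply(manifest$genomes[ids],
                   function(g) g$taxonomy[[rank]], character(1))
  if (!any(nzchar(labels))) stop("no genome is labelled at rank ", rank)
  keep <- which(nzchar(labels))
  breaks <- seq(0, 1, by = 0.02)
  strat <- function(values, label) {
    counts <- as.vector(table(cut(pmin(values, 1), breaks = breaks,
                                  include.lowest = TRUE, right = FALSE)))
    # right-closed top bin: cut(..., right = FALSE) puts 1 in the last
    # interval via include.lowest
    list(breaks = breaks, counts = counts, distances = values,
         stratum = label)
  }
  same <- outer(labels[keep], labels[keep], "==")
  ut <- upper.tri(same)
  sub <- D[keep, keep, drop = FALSE]
  list(within = strat(sub[ut][same[ut]], paste0("within-", rank)),
       between = strat(sub[ut][!same[ut]], paste0("between-", rank)))
}

#' Export pairwise distances in long format
#'
#' One row per unordered genome pair with the distance and same-family
#' / same-genus indicators (empty labels give NA).
#'
#' @param D A `cgj_distance_matrix`.
#' @param manifest The `cgj_manifest`.
#' @param path Optional TSV output path.
#' @return The long-format data frame, invisibly when `path` is given.
#' @export
distance_pairs <- function(D, manifest, path = NULL) {
  ids <- rownames(D)
  idx <- which(upper.tri(D), arr.ind = TRUE)
  lab <- function(rank) vapply(manifest$genomes[ids],
                               function(g) g$taxonomy[[rank]], character(1))
  fam <- lab("family"); gen <- lab("genus")
  cmp <- function(v) {
    out <- v[idx[, 1]] == v[idx[, 2]]
    out[!nzchar(v[idx[, 1]]) | !nzchar(v[idx[, 2]])] <- NA
    out
  }
  df <- data.frame(id_a = ids[idx[, 1]], id_b = ids[idx[, 2]],
                   distance = D[idx],
                   same_family = cmp(fam), same_genus = cmp(gen),
                   stringsAsFactors = FALSE)
  if (!is.null(path)) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(df))
  }
  df
}
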