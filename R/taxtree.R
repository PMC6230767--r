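# UPGMA dendrograms on CGJ distances, signature-table bootstrap,
# threshold collapse into family-equivalent clusters, heat-map leaf
# ordering and assignment of unclassified genomes.
#
# A dendrogram (S3 "cgj_dendrogram") stores, hclust-style:
#   labels  leaf genome ids
#   merge   (n-1) x 2; negative entries index leaves, positive entries
#           earlier merge rows
#   height  merge heights on the CGJ-distance scale (full merge
#           distance, matching the 0.8 family threshold scale)
#   support optional bootstrap support per merge row, in [0, 100]

#' UPGMA dendrogram from a distance matrix
#'
#' Iteratively merges the closest pair of clusters; the merged
#' cluster's distance to any other is the size-weighted arithmetic mean
#' of its parts' distances. Ties are broken by the lexicographically
#' smallest pair of cluster anchor ids (each cluster's smallest member
#' id), which makes the result invariant to input ordering.
#'
#' @param D Symmetric distance matrix with row/column names (e.g. a
#'   `cgj_distance_matrix`).
#' @return A `cgj_dendrogram`.
#' @export
upgma <- function(D) {
  D <- unclass(D)
  if (any(is.na(D))) stop("NaN/NA in distance matrix")
  n <- nrow(D)
  if (n < 2L) stop("UPGMA needs at least 2 genomes")
  labels <- rownames(D)
  if (is.null(labels)) labels <- as.character(seq_len(n))

  # active cluster bookkeeping
  node <- as.list(-seq_len(n))      # hclust code of each active cluster
  size <- rep(1L, n)
  anchor <- labels                  # smallest member id per cluster
  d <- D
  diag(d) <- Inf
  active <- rep(TRUE, n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)

  for (step in seq_len(n - 1L)) {
    idx <- which(active)
    sub <- d[idx, idx, drop = FALSE]
    mn <- min(sub)
    cand <- which(sub == mn, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    keys <- apply(cand, 1, function(rc) {
      a <- sort(c(anchor[idx[rc[1]]], anchor[idx[rc[2]]]))
      paste(a, collapse = "\r")
    })
    pick <- cand[order(keys)[1], ]
    i <- idx[pick[1]]; j <- idx[pick[2]]
    if (anchor[j] < anchor[i]) { tmp <- i; i <- j; j <- tmp }

    merge[step, ] <- c(node[[i]], node[[j]])
    height[step] <- mn
    # size-weighted average linkage update, stored in slot i
    others <- setdiff(idx, c(i, j))
    if (length(others)) {
      d[i, others] <- d[others, i] <-
        (size[i] * d[i, others] + size[j] * d[j, others]) / (size[i] + size[j])
    }
    size[i] <- size[i] + size[j]
    node[[i]] <- step
    anchor[i] <- min(anchor[i], anchor[j])
    active[j] <- FALSE
    d[j, ] <- d[, j] <- Inf
  }
  structure(list(labels = labels, merge = merge, height = height,
                 support = NULL),
            class = "cgj_dendrogram")
}

#' @export
print.cgj_dendrogram <- function(x, ...) {
  cat(sprintf("<cgj_dendrogram> %d leaves, root height %.4f%s\n",
              length(x$labels), max(x$height),
              if (is.null(x$support)) "" else ", with bootstrap supports"))
  invisible(x)
}

# leaf index sets (into labels) for every merge row
clade_leafsets <- function(tree) {
  sets <- vector("list", nrow(tree$merge))
  grab <- function(code) {
    if (code < 0) -code else sets[[code]]
  }
  for (r in seq_len(nrow(tree$merge))) {
    sets[[r]] <- c(grab(tree$merge[r, 1]), grab(tree$merge[r, 2]))
  }
  sets
}

#' Cophenetic distance matrix of a dendrogram
#'
#' @param tree A `cgj_dendrogram`.
#' @return Symmetric matrix of merge heights between leaf pairs.
#' @export
cophenetic_matrix <- function(tree) {
  n <- length(tree$labels)
  C <- matrix(0, n, n, dimnames = list(tree$labels, tree$labels))
  sets <- clade_leafsets(tree)
  grab <- function(code) if (code < 0) -code else sets[[code]]
  for (r in seq_len(nrow(tree$merge))) {
    a <- grab(tree$merge[r, 1]); b <- grab(tree$merge[r, 2])
    C[a, b] <- C[b, a] <- tree$height[r]
  }
  C
}

#' Bootstrap clade supports from a signature table
#'
#' Builds the dendrogram from the full table, then for each
#' pseudoreplicate resamples PPHMM columns with replacement (keeping
#' the GOM columns fixed, since they derive from the same gene set;
#' `resample = "joint"` also resamples the GOM columns), recomputes the
#' distance matrix and UPGMA tree, and scores each original clade by
#' the percentage of replicate trees containing the same leaf set.
#'
#' @param table A `cgj_signature_table` with at least 2 PPHMM columns.
#' @param n_reps Number of pseudoreplicates (50-100 typical).
#' @param seed RNG seed; results are reproducible given the seed.
#' @param resample `"pphmm"` (default) or `"joint"`.
#' @return The original `cgj_dendrogram` with `support` filled in
#'   (percentages in \[0, 100\] per internal node).
#' @export
bootstrap_supports <- function(table, n_reps = 100, seed = 1,
                               resample = c("pphmm", "joint")) {
  resample <- match.arg(resample)
  if (n_reps < 1) stop("n_reps must be at least 1")
  if (ncol(table$pphmm_block) < 2L) {
    stop("bootstrap needs at least 2 PPHMM columns")
  }
  tree <- upgma(distance_matrix(table))
  sets <- clade_leafsets(tree)
  keys <- vapply(sets, function(s)
    paste(sort(tree$labels[s]), collapse = "\r"), character(1))
  hits <- stats::setNames(numeric(length(keys)), keys)
  np <- ncol(table$pphmm_block)
  ng <- ncol(table$gom_block)
  with_rng_seed(seed, {
    for (b in seq_len(n_reps)) {
      pi <- sample.int(np, np, replace = TRUE)
      rt <- table
      rt$pphmm_block <- table$pphmm_block[, pi, drop = FALSE]
      rt$locations <- table$locations[, pi, drop = FALSE]
      if (resample == "joint" && ng > 0L) {
        gi <- sample.int(ng, ng, replace = TRUE)
        rt$gom_block <- table$gom_block[, gi, drop = FALSE]
      }
      bt <- upgma(distance_matrix(rt))
      bsets <- clade_leafsets(bt)
      bkeys <- unique(vapply(bsets, function(s)
        paste(sort(bt$labels[s]), collapse = "\r"), character(1)))
      present <- keys %in% bkeys
      hits[present] <- hits[present] + 1
    }
  })
  tree$support <- unname(100 * hits / n_reps)
  tree
}

#' Collapse a dendrogram at a distance threshold
#'
#' Clusters are the maximal clades whose root height is strictly below
#' the threshold; leaves only attached above it become singletons. With
#' taxonomy available a per-cluster composition summary is included.
#'
#' @param tree A `cgj_dendrogram`.
#' @param threshold Collapse height on the CGJ-distance scale; 0.8
#'   corresponds to the family-level divergence cut-off.
#' @param manifest Optional `cgj_manifest` for composition summaries.
#' @return Object of class `cgj_partition`: `threshold`, `clusters`
#'   (list of genome-id vectors) and `summary` (data frame).
#' @export
collapse <- function(tree, threshold = 0.8, manifest = NULL) {
  if (!is.numeric(threshold) || threshold < 0 || threshold > 1) {
    stop("threshold must lie in [0, 1]")
  }
  n <- length(tree$labels)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  sets <- clade_leafsets(tree)
  for (r in seq_len(nrow(tree$merge))) {
    if (tree$height[r] < threshold) {
      s <- sets[[r]]
      root <- find(s[1])
      for (x in s[-1]) parent[find(x)] <- root
    }
  }
  groups <- split(seq_len(n), vapply(seq_len(n), find, integer(1)))
  clusters <- lapply(groups, function(g) sort(tree$labels[g]))
  clusters <- clusters[order(vapply(clusters, `[`, character(1), 1))]
  names(clusters) <- sprintf("CL%04d", seq_along(clusters))
  summary <- cluster_summary(clusters, manifest)
  structure(list(threshold = threshold, clusters = clusters,
                 summary = summary),
            class = "cgj_partition")
}

cluster_summary <- function(clusters, manifest) {
  if (is.null(manifest)) {
    return(data.frame(cluster_id = names(clusters),
                      n = lengths(clusters),
                      stringsAsFactors = FALSE, row.names = NULL))
  }
  rows <- lapply(names(clusters), function(cid) {
    ids <- clusters[[cid]]
    cls <- manifest$classified[ids]
    fam <- vapply(manifest$genomes[ids],
                  function(g) g$taxonomy[["family"]], character(1))
    host <- vapply(manifest$genomes[ids],
                   function(g) g$taxonomy[["host_group"]], character(1))
    data.frame(cluster_id = cid, n = length(ids),
               n_classified = sum(cls), n_unclassified = sum(!cls),
               families = paste(sort(unique(fam[nzchar(fam)])),
                                collapse = ";"),
               host_groups = paste(sort(unique(host[nzchar(host)])),
                                   collapse = ";"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' @export
print.cgj_partition <- function(x, ...) {
  cat(sprintf("<cgj_partition> %d clusters at threshold %.2f\n",
              length(x$clusters), x$threshold))
  invisible(x)
}

#' Assign unclassified genomes to collapsed clusters
#'
#' Labels every unclassified genome with its cluster and the families
#' of the classified genomes it clusters with. Clusters containing only
#' unclassified genomes are flagged as candidate unassigned taxonomic
#' units (UTUs). Genomes whose PPHMM signature is zero on every PPHMM
#' with at least one classified member virus (all PPHMMs when no
#' database is supplied) are reported as showing no similarity to any
#' sequence in the classified dataset.
#'
#' @param partition A `cgj_partition` built over classified and
#'   unclassified genomes jointly.
#' @param manifest The `cgj_manifest`.
#' @param table Optional `cgj_signature_table` used to detect all-zero
#'   signatures.
#' @param db Optional `cgj_pphmm_db`; restricts the no-similarity
#'   check to PPHMMs with classified members.
#' @return Data frame with one row per unclassified genome:
#'   `genome_id`, `cluster_id`, `cluster_families`, `n_classified`,
#'   `is_utu`, `no_similarity`.
#' @export
assign_unclassified <- function(partition, manifest, table = NULL,
                                db = NULL) {
  uncls <- names(manifest$classified)[!manifest$classified]
  ref_cols <- if (!is.null(table)) {
    if (!is.null(db)) {
      cls_ids <- names(manifest$classified)[manifest$classified]
      names(db$pphmms)[vapply(db$pphmms, function(p)
        any(p$member_virus_ids %in% cls_ids), logical(1))]
    } else colnames(table$pphmm_block)
  } else character()
  cl_of <- stats::setNames(
    rep(names(partition$clusters), lengths(partition$clusters)),
    unlist(partition$clusters))
  rows <- lapply(uncls, function(gid) {
    cid <- cl_of[[gid]]
    ids <- partition$clusters[[cid]]
    cls <- manifest$classified[ids]
    fam <- vapply(manifest$genomes[ids[cls]],
                  function(g) g$taxonomy[["family"]], character(1))
    zero <- if (!is.null(table)) {
      all(table$pphmm_block[gid, ref_cols] == 0)
    } else FALSE
    data.frame(genome_id = gid, cluster_id = cid,
               cluster_families = paste(sort(unique(fam[nzchar(fam)])),
                                        collapse = ";"),
               n_classified = sum(cls),
               is_utu = !any(cls),
               no_similarity = zero,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Heat-map leaf order of a dendrogram
#'
#' Left-to-right leaf order under a deterministic child ordering: the
#' lower-height child first, ties resolved by the smallest leaf id in
#' each child.
#'
#' @param tree A `cgj_dendrogram`.
#' @return Character vector of genome ids (a permutation of the
#'   leaves).
#' @export
leaf_order_for_heatmap <- function(tree) {
  sets <- clade_leafsets(tree)
  child_height <- function(code) if (code < 0) 0 else tree$height[code]
  child_minlab <- function(code) {
    if (code < 0) tree$labels[-code] else min(tree$labels[sets[[code]]])
  }
  rec <- function(code) {
    if (code < 0) return(tree$labels[-code])
    ch <- tree$merge[code, ]
    h <- vapply(ch, child_height, numeric(1))
    ml <- vapply(ch, child_minlab, character(1))
    ord <- order(h, ml)
    c(rec(ch[ord[1]]), rec(ch[ord[2]]))
  }
  rec(nrow(tree$merge))
}

#' Write a dendrogram in Newick format
#'
#' Branch lengths are height differences between a node and its parent;
#' bootstrap supports (when present) become internal node labels.
#'
#' @param tree A `cgj_dendrogram`.
#' @param path Optional output file; when `NULL` the Newick string is
#'   returned.
#' @return The Newick string, invisibly when written to `path`.
#' @export
write_newick <- function(tree, path = NULL) {
  rec <- function(code, parent_h) {
    if (code < 0) {
      return(sprintf("%s:%.10g", gsub("[,;:() \t]", "_",
                                      tree$labels[-code]), parent_h))
    }
    h <- tree$height[code]
    lab <- if (!is.null(tree$support)) sprintf("%.6g", tree$support[code]) else ""
    sprintf("(%s,%s)%s:%.10g",
            rec(tree$merge[code, 1], h), rec(tree$merge[code, 2], h),
            lab, parent_h - h)
  }
  root <- nrow(tree$merge)
  h <- tree$height[root]
  lab <- if (!is.null(tree$support)) sprintf("%.6g", tree$support[root]) else ""
  nwk <- sprintf("(%s,%s)%s;", rec(tree$merge[root, 1], h),
                 rec(tree$merge[root, 2], h), lab)
  if (!is.null(path)) {
    writeLines(nwk, path)
    return(invisible(nwk))
  }
  nwk
}
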