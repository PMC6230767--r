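# Per-genome PPHMM signatures and signed gene-location profiles,
# per-family genome-organisation models (GOMs), and GOM signatures via
# distance correlation.
#
# A signature table (S3 "cgj_signature_table") has:
#   genome_ids   character vector (row order of all blocks)
#   pphmm_block  genomes x PPHMMs matrix of bit scores (absent -> 0)
#   gom_block    genomes x families matrix of GOM scores in [0,1]
#   locations    genomes x PPHMMs matrix of signed fractional midpoints
#   pphmm_ids, family_ids  column metadata

#' Signed gene-location profile of one genome
#'
#' Each PPHMM with a hit contributes `s * m` where `m` is the hit
#' feature's fractional midpoint in (0, 1] over the concatenated genome
#' length and `s` is +1 on the forward strand, -1 on the reverse;
#' absent PPHMMs contribute 0. The sign makes gene orientation, and the
#' magnitude gene order, visible to the distance-correlation statistic.
#'
#' @param hits Best-hit-deduplicated hit table from [scan_genome()].
#' @param genome The genome scanned.
#' @param pphmm_ids Database column order.
#' @return Named numeric vector over `pphmm_ids`, entries in \[-1, 1\].
#' @export
location_profile <- function(hits, genome, pphmm_ids) {
  prof <- stats::setNames(rep(0, length(pphmm_ids)), pphmm_ids)
  if (nrow(hits)) {
    if (any(hits$midpoint <= 0 | hits$midpoint > 1)) {
      stop("hit midpoint outside the genome for ", genome$genome_id)
    }
    if (anyDuplicated(hits$pphmm_id)) {
      stop("hits must contain at most one row per PPHMM")
    }
    prof[hits$pphmm_id] <- ifelse(hits$strand == "-", -1, 1) * hits$midpoint
  }
  prof
}

#' Genome-organisation model of one family
#'
#' Stacks the signed gene-location profiles of the family's member
#' genomes into a matrix, rows in sorted genome-id order.
#'
#' @param family_id Family label.
#' @param profiles Named list (or matrix rows) of member location
#'   profiles.
#' @return An object of class `cgj_gom` with fields `family_id` and
#'   `profiles` (members x PPHMMs matrix).
#' @export
build_gom <- function(family_id, profiles) {
  if (length(profiles) == 0L) stop("GOM for ", family_id, " has no members")
  m <- do.call(rbind, profiles[order(names(profiles))])
  rownames(m) <- sort(names(profiles))
  structure(list(family_id = family_id, profiles = m), class = "cgj_gom")
}

#' Sample distance correlation between a profile and a GOM
#'
#' Treats the `m` PPHMM columns as observations: scalar observations
#' `x_j` against the k-dimensional column vectors of `Y`. Pairwise
#' distances `a_jl = |x_j - x_l|` and `b_jl = ||Y_j - Y_l||` are
#' double-centered and combined into the classic (biased) sample
#' distance correlation of Szekely and Rizzo, computed here through the
#' S1/S2/S3 moment identities. Degenerate inputs (either distance
#' variance zero, e.g. a constant profile) return 0: no organisational
#' evidence, rather than NaN.
#'
#' @param x Numeric vector of length m.
#' @param Y Numeric matrix with m columns (k rows).
#' @return Distance correlation in \[0, 1\].
#' @export
distance_correlation <- function(x, Y) {
  Y <- rbind(Y)
  m <- length(x)
  if (m < 2L) stop("distance correlation needs at least 2 observations")
  if (ncol(Y) != m) stop("Y must have as many columns as x has entries")
  a <- abs(outer(x, x, "-"))
  b <- as.matrix(stats::dist(t(Y), method = "euclidean"))
  dcov2 <- function(a, b) {
    S1 <- mean(a * b)
    S2 <- mean(a) * mean(b)
    S3 <- mean(rowMeans(a) * rowMeans(b))
    S1 + S2 - 2 * S3
  }
  vx <- dcov2(a, a)
  vy <- dcov2(b, b)
  if (vx <= 0 || vy <= 0) return(0)
  r2 <- dcov2(a, b) / sqrt(vx * vy)
  sqrt(max(0, min(1, r2)))
}

#' GOM signature of one genome
#'
#' @param profile Signed location profile of the genome.
#' @param goms Named list of `cgj_gom` objects.
#' @return Numeric vector of distance correlations, one per family GOM.
#' @export
gom_signature <- function(profile, goms) {
  vapply(goms, function(g) distance_correlation(profile, g$profiles),
         numeric(1))
}

#' Build family GOMs from a manifest's hits
#'
#' One GOM per family among the classified genomes; families without a
#' label are skipped.
#'
#' @param profiles Genomes x PPHMMs matrix of location profiles.
#' @param manifest The `cgj_manifest`.
#' @return Named list of `cgj_gom`, alphabetical by family.
#' @export
build_family_goms <- function(profiles, manifest) {
  fams <- vapply(manifest$genomes, function(g) g$taxonomy[["family"]],
                 character(1))
  use <- manifest$classified & nzchar(fams)
  fam_split <- split(names(fams)[use], fams[use])
  goms <- lapply(names(fam_split), function(fam) {
    ids <- fam_split[[fam]]
    build_gom(fam, stats::setNames(
      lapply(ids, function(i) profiles[i, ]), ids))
  })
  stats::setNames(goms, names(fam_split))[sort(names(fam_split))]
}

#' Annotate every genome with PPHMM and GOM signatures
#'
#' Scans each genome of the manifest (classified and unclassified)
#' against the PPHMM database, derives signed location profiles, builds
#' one GOM per family from the classified genomes, and scores every
#' genome's profile against every family GOM by distance correlation.
#' Deterministic given its inputs.
#'
#' @param manifest A `cgj_manifest`.
#' @param db A `cgj_pphmm_db`.
#' @param goms Optional precomputed GOM list; built from the manifest's
#'   classified genomes when `NULL`.
#' @param score_floor Hit acceptance floor in bits (see
#'   [scan_genome()]).
#' @return A `cgj_signature_table`.
#' @export
build_signature_table <- function(manifest, db, goms = NULL,
                                  score_floor = 0) {
  ids <- names(manifest$genomes)
  pids <- names(db$pphmms)
  scores <- matrix(0, length(ids), length(pids),
                   dimnames = list(ids, pids))
  locs <- matrix(0, length(ids), length(pids),
                 dimnames = list(ids, pids))
  for (gid in ids) {
    h <- scan_genome(manifest$genomes[[gid]], db, score_floor)
    if (nrow(h)) {
      scores[gid, h$pphmm_id] <- h$score
      locs[gid, ] <- location_profile(h, manifest$genomes[[gid]], pids)
    }
  }
  if (is.null(goms)) goms <- build_family_goms(locs, manifest)
  fam_ids <- names(goms)
  gom_block <- matrix(0, length(ids), length(fam_ids),
                      dimnames = list(ids, fam_ids))
  if (length(fam_ids) && length(pids) >= 2L) {
    for (gid in ids) gom_block[gid, ] <- gom_signature(locs[gid, ], goms)
  }
  new_signature_table(ids, scores, gom_block, locs)
}

new_signature_table <- function(ids, pphmm_block, gom_block, locations) {
  stopifnot_named(
    "signature blocks must share row order" =
      identical(rownames(pphmm_block), ids) &&
      identical(rownames(gom_block), ids),
    "signature table has missing values" =
      all(is.finite(pphmm_block)) && all(is.finite(gom_block))
  )
  structure(list(genome_ids = ids,
                 pphmm_block = pphmm_block,
                 gom_block = gom_block,
                 locations = locations,
                 pphmm_ids = colnames(pphmm_block),
                 family_ids = colnames(gom_block)),
            class = "cgj_signature_table")
}

#' @export
print.cgj_signature_table <- function(x, ...) {
  cat(sprintf("<cgj_signature_table> %d genomes x (%d PPHMMs + %d GOMs)\n",
              length(x$genome_ids), length(x$pphmm_ids),
              length(x$family_ids)))
  invisible(x)
}

#' Subsample a signature table to a genome and family subset
#'
#' Restricts rows to `genome_subset`, drops PPHMM columns whose scores
#' are zero for every retained genome, and restricts GOM columns to
#' `family_subset` so that organisation scores not pertaining to the
#' investigated families are excluded.
#'
#' @param table A `cgj_signature_table`.
#' @param genome_subset Genome ids to keep (default all).
#' @param family_subset Family ids to keep (default all).
#' @return The pruned `cgj_signature_table`.
#' @export
subset_signature_table <- function(table, genome_subset = table$genome_ids,
                                   family_subset = table$family_ids) {
  if (!length(genome_subset)) stop("empty genome subset")
  if (!all(genome_subset %in% table$genome_ids)) {
    stop("unknown genome id in subset")
  }
  pb <- table$pphmm_block[genome_subset, , drop = FALSE]
  keep_p <- colSums(pb > 0) > 0
  if (!any(keep_p)) stop("subset leaves no non-zero PPHMM column")
  gb <- table$gom_block[genome_subset, intersect(family_subset,
                                                 table$family_ids),
                        drop = FALSE]
  new_signature_table(genome_subset,
                      pb[, keep_p, drop = FALSE], gb,
                      table$locations[genome_subset, keep_p, drop = FALSE])
}

#' Export a signature table as TSV
#'
#' Columns are `pphmm:<id>` then `gom:<family>`; a companion file with
#' suffix `.locations.tsv` carries the signed location profiles.
#'
#' @param table A `cgj_signature_table`.
#' @param path Output TSV path.
#' @export
write_signature_table <- function(table, path) {
  m <- cbind(table$pphmm_block, table$gom_block)
  colnames(m) <- c(paste0("pphmm:", table$pphmm_ids),
                   paste0("gom:", table$family_ids))
  write_table(m, path, kind = "signatures")
  lp <- table$locations
  colnames(lp) <- paste0("pphmm:", colnames(lp))
  write_table(lp, sub("\\.tsv$", ".locations.tsv", path),
              kind = "signatures")
  invisible(NULL)
}
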