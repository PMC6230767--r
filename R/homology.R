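# All-vs-all protein similarity, clustering into putative gene
# families, per-cluster alignment, profile-HMM construction and genome
# scanning.

#' Define the protein scoring system
#'
#' Local (Smith-Waterman) alignment scores are reported in bits via the
#' Karlin-Altschul transform `(lambda * S - ln K) / ln 2`. The fixed
#' gapped-BLOSUM62 constants are used for every pair: the bit scale only
#' needs to be internally consistent because downstream statistics are
#' ratios of scores (generalized Jaccard), not significance tests.
#'
#' A gap of length g costs `gap_open + (g - 1) * gap_extend`.
#'
#' @param matrix Substitution matrix name (`"BLOSUM62"`, `"BLOSUM50"`,
#'   ...; resolved from the Biostrings data sets) or a numeric matrix.
#' @param gap_open Cost of the first residue of a gap.
#' @param gap_extend Cost of each subsequent gap residue.
#' @param lambda,K Karlin-Altschul scale constants.
#' @return A list of class `cgj_scoring`.
#' @export
scoring_system <- function(matrix = "BLOSUM62", gap_open = 11,
                           gap_extend = 1, lambda = 0.267, K = 0.041) {
  if (is.character(matrix)) {
    e <- new.env()
    utils::data(list = matrix, package = "Biostrings", envir = e)
    matrix <- get(matrix, envir = e)
  }
  structure(list(matrix = matrix, gap_open = gap_open,
                 gap_extend = gap_extend, lambda = lambda, K = K),
            class = "cgj_scoring")
}

bit_score <- function(raw, scoring) {
  (scoring$lambda * raw - log(scoring$K)) / log(2)
}

# Biostrings charges gapOpening + g * gapExtension for a length-g gap;
# our convention charges gap_open for the first residue.
bs_gap <- function(scoring) {
  list(opening = scoring$gap_open - scoring$gap_extend,
       extension = scoring$gap_extend)
}

#' Raw Smith-Waterman local alignment score
#'
#' @param a,b Amino-acid strings.
#' @param scoring A [scoring_system()].
#' @return Raw local alignment score (0 if no positive-scoring local
#'   alignment exists).
#' @export
sw_score <- function(a, b, scoring = scoring_system()) {
  if (!nzchar(a) || !nzchar(b)) stop("empty protein sequence")
  g <- bs_gap(scoring)
  max(0, Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
    substitutionMatrix = scoring$matrix, gapOpening = g$opening,
    gapExtension = g$extension, scoreOnly = TRUE))
}

#' All-vs-all protein similarity edges
#'
#' Computes local-alignment bit scores for every unordered protein pair
#' and keeps edges at or above `min_score` bits. Scores are symmetric by
#' construction (each pair is aligned once).
#'
#' @param proteins Data frame with columns `feature_id`, `genome_id`,
#'   `translation` (e.g. from [manifest_proteins()]).
#' @param scoring A [scoring_system()].
#' @param min_score Minimum bit score for an edge to be reported.
#' @return Data frame with columns `protein_a`, `protein_b`,
#'   `bit_score`, one row per retained unordered pair.
#' @export
pairwise_similarity <- function(proteins, scoring = scoring_system(),
                                min_score = 30) {
  n <- nrow(proteins)
  if (n < 2L) stop("need at least 2 proteins")
  if (any(!nzchar(proteins$translation))) stop("empty protein sequence")
  seqs <- Biostrings::AAStringSet(proteins$translation)
  names(seqs) <- proteins$feature_id
  g <- bs_gap(scoring)
  out <- vector("list", n - 1L)
  for (j in 2:n) {
    raw <- Biostrings::pairwiseAlignment(
      seqs[1:(j - 1L)], seqs[[j]], type = "local",
      substitutionMatrix = scoring$matrix, gapOpening = g$opening,
      gapExtension = g$extension, scoreOnly = TRUE)
    bits <- bit_score(pmax(raw, 0), scoring)
    keep <- which(bits >= min_score)
    if (length(keep)) {
      out[[j - 1L]] <- data.frame(
        protein_a = proteins$feature_id[keep],
        protein_b = proteins$feature_id[j],
        bit_score = bits[keep], stringsAsFactors = FALSE)
    }
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) {
    return(data.frame(protein_a = character(), protein_b = character(),
                      bit_score = numeric(), stringsAsFactors = FALSE))
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Import externally computed similarity scores
#'
#' Reads a 3-column TSV (`id_a`, `id_b`, `bit_score`), e.g. from a
#' faster external search engine, into the edge-list format produced by
#' [pairwise_similarity()]. Duplicate unordered pairs keep the maximum
#' score.
#'
#' @param path TSV path (header optional).
#' @return Edge data frame.
#' @export
import_similarity_scores <- function(path) {
  df <- utils::read.delim(path, header = FALSE, col.names =
                            c("protein_a", "protein_b", "bit_score"),
                          colClasses = c("character", "character", "numeric"),
                          comment.char = "#")
  if (nrow(df) && is.na(suppressWarnings(as.numeric(df$bit_score[1])))) {
    df <- df[-1, , drop = FALSE]  # header row
  }
  df$bit_score <- as.numeric(df$bit_score)
  key <- ifelse(df$protein_a < df$protein_b,
                paste(df$protein_a, df$protein_b),
                paste(df$protein_b, df$protein_a))
  df <- df[order(key, -df$bit_score), ]
  df <- df[!duplicated(key[order(key, -df$bit_score)]), ]
  rownames(df) <- NULL
  df
}

#' Cluster proteins into putative gene families
#'
#' The default method takes connected components of the similarity
#' graph restricted to edges at or above `threshold` bits; proteins
#' without qualifying edges form singleton clusters. The `mcl_like`
#' method runs a Markov-cluster style expansion/inflation iteration on
#' the thresholded graph. Both are deterministic and invariant to the
#' order of the edge list; cluster ids follow the sorted smallest member
#' feature id.
#'
#' @param edges Edge data frame from [pairwise_similarity()].
#' @param proteins Protein data frame (all proteins, including those
#'   without edges).
#' @param method `"components"` or `"mcl_like"`.
#' @param threshold Minimum bit score for an edge to connect.
#' @param inflation Inflation exponent for `mcl_like`.
#' @return List of clusters; each has `cluster_id`, `members` (data
#'   frame `genome_id`, `feature_id`) and `n_member_viruses`.
#' @export
cluster_proteins <- function(edges, proteins,
                             method = c("components", "mcl_like"),
                             threshold = 30, inflation = 2) {
  method <- match.arg(method)
  ids <- proteins$feature_id
  keep <- edges[edges$bit_score >= threshold, , drop = FALSE]
  membership <- if (method == "components" || nrow(keep) == 0L) {
    g <- igraph::graph_from_data_frame(
      keep[, c("protein_a", "protein_b")], directed = FALSE,
      vertices = data.frame(name = ids))
    igraph::components(g)$membership[ids]
  } else {
    mcl_membership(keep, ids, inflation)
  }
  split_ids <- split(ids, membership)
  # order clusters by their smallest member feature id
  anchors <- vapply(split_ids, function(v) min(v), character(1))
  split_ids <- split_ids[order(anchors)]
  lapply(seq_along(split_ids), function(i) {
    members_id <- sort(split_ids[[i]])
    rows <- match(members_id, proteins$feature_id)
    list(cluster_id = sprintf("PC%04d", i),
         members = data.frame(genome_id = proteins$genome_id[rows],
                              feature_id = members_id,
                              stringsAsFactors = FALSE),
         n_member_viruses = length(unique(proteins$genome_id[rows])))
  })
}

# Deterministic MCL-style clustering on the thresholded graph: column
# normalisation, expansion (squaring), elementwise inflation, pruning,
# attractor extraction. Applied per connected component.
mcl_membership <- function(edges, ids, inflation) {
  n <- length(ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  ia <- match(edges$protein_a, ids)
  ib <- match(edges$protein_b, ids)
  A[cbind(ia, ib)] <- edges$bit_score
  A[cbind(ib, ia)] <- edges$bit_score
  diag(A) <- pmax(apply(A, 1, max), 1)  # self loops
  M <- sweep(A, 2, colSums(A), "/")
  for (it in 1:100) {
    M2 <- M %*% M
    M2 <- M2 ^ inflation
    M2 <- sweep(M2, 2, colSums(M2), "/")
    M2[M2 < 1e-8] <- 0
    M2 <- sweep(M2, 2, colSums(M2), "/")
    if (max(abs(M2 - M)) < 1e-10) { M <- M2; break }
    M <- M2
  }
  attract <- which(diag(M) > 1e-4)
  memb <- integer(n)
  cl <- 0L
  for (a in attract) {
    nodes <- which(M[a, ] > 1e-4)
    if (all(memb[c(a, nodes)] == 0L)) {
      cl <- cl + 1L
      memb[c(a, nodes)] <- cl
    } else {
      ex <- setdiff(unique(memb[c(a, nodes)]), 0L)[1]
      memb[c(a, nodes)][memb[c(a, nodes)] == 0L] <- ex
      memb[c(a, nodes)] <- ex
    }
  }
  if (any(memb == 0L)) memb[memb == 0L] <- cl + seq_len(sum(memb == 0L))
  stats::setNames(memb, ids)
}

#' Center-star multiple alignment of a protein cluster
#'
#' The center is the member with the greatest summed pairwise bit score
#' against the other members; every other member is globally aligned to
#' the center and the pairwise alignments are merged on the center's
#' coordinates (a gap inserted into the center by any member is
#' propagated to all rows).
#'
#' @param cluster One cluster from [cluster_proteins()].
#' @param proteins Protein data frame with `feature_id`, `translation`.
#' @param scoring A [scoring_system()].
#' @return Named character vector of equal-length gapped rows, one per
#'   member, in the cluster's member order.
#' @export
align_cluster <- function(cluster, proteins, scoring = scoring_system()) {
  ids <- cluster$members$feature_id
  seqs <- proteins$translation[match(ids, proteins$feature_id)]
  names(seqs) <- ids
  if (length(ids) == 1L) return(seqs)
  if (length(unique(seqs)) == 1L) {
    return(stats::setNames(rep(seqs[[1]], length(ids)), ids))
  }
  g <- bs_gap(scoring)
  # center: greatest summed pairwise raw SW score
  sums <- numeric(length(ids))
  for (i in seq_along(ids)) {
    raw <- Biostrings::pairwiseAlignment(
      Biostrings::AAStringSet(seqs[-i]), Biostrings::AAString(seqs[[i]]),
      type = "local", substitutionMatrix = scoring$matrix,
      gapOpening = g$opening, gapExtension = g$extension, scoreOnly = TRUE)
    sums[i] <- sum(bit_score(pmax(raw, 0), scoring))
  }
  ci <- which.max(sums)
  center <- seqs[[ci]]
  others <- setdiff(seq_along(ids), ci)
  L <- nchar(center)

  # For each non-center member, record inserted residues before each
  # center position (slot L+1 = after the last residue) and the member
  # residue aligned to each center position ("-" for a deletion).
  ins <- matrix(0L, nrow = length(others), ncol = L + 1L)
  ins_str <- matrix("", nrow = length(others), ncol = L + 1L)
  aligned <- matrix("-", nrow = length(others), ncol = L)
  for (r in seq_along(others)) {
    o <- others[r]
    al <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(center), Biostrings::AAString(seqs[[o]]),
      type = "global", substitutionMatrix = scoring$matrix,
      gapOpening = g$opening, gapExtension = g$extension)
    pa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
    sa <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
    pos <- 0L
    for (c in seq_along(pa)) {
      if (pa[c] == "-") {
        slot <- pos + 1L
        ins[r, slot] <- ins[r, slot] + 1L
        ins_str[r, slot] <- paste0(ins_str[r, slot], sa[c])
      } else {
        pos <- pos + 1L
        aligned[r, pos] <- sa[c]
      }
    }
  }
  ins_max <- apply(ins, 2, max)
  pad <- function(s, w) paste0(strrep("-", w - nchar(s)), s)
  center_chars <- strsplit(center, "")[[1]]
  build_row <- function(res_at, ins_at) {
    parts <- character(0)
    for (k in seq_len(L)) {
      parts <- c(parts, pad(ins_at[k], ins_max[k]), res_at[k])
    }
    paste0(paste(parts, collapse = ""), pad(ins_at[L + 1L], ins_max[L + 1L]))
  }
  rows <- character(length(ids))
  rows[ci] <- build_row(center_chars, rep("", L + 1L))
  for (r in seq_along(others)) {
    rows[others[r]] <- build_row(aligned[r, ], ins_str[r, ])
  }
  stats::setNames(rows, ids)
}

#' Build a protein profile HMM from a multiple alignment
#'
#' Match states are alignment columns whose gap fraction does not
#' exceed 0.5. Match emissions are column residue counts plus
#' background-weighted pseudocounts of total strength `alpha`,
#' normalised; insert states emit the background. Transition
#' probabilities are estimated from per-row match/insert/delete state
#' paths with pseudocount 1 per transition type.
#'
#' @param msa Character vector of equal-length gapped rows.
#' @param cluster Cluster the alignment came from (supplies the id and
#'   member bookkeeping); may be `NULL` for ad-hoc models.
#' @param alpha Pseudocount strength for match emissions.
#' @param background Length-20 amino-acid background distribution.
#' @return An object of class `cgj_pphmm`.
#' @export
build_pphmm <- function(msa, cluster = NULL, alpha = 1,
                        background = AA_BACKGROUND) {
  if (length(msa) == 0L) stop("empty alignment")
  if (length(unique(nchar(msa))) != 1L) stop("MSA rows have unequal lengths")
  rows <- strsplit(msa, "")
  ncol_al <- nchar(msa[[1]])
  nrow_al <- length(msa)
  colmat <- do.call(rbind, rows)
  gap_frac <- colMeans(colmat == "-")
  is_match <- gap_frac <= 0.5
  L <- sum(is_match)
  if (L == 0L) stop("alignment yields no match states")
  match_idx <- cumsum(is_match)

  # emissions
  emis <- matrix(0, nrow = L, ncol = 20, dimnames = list(NULL, AA20))
  mcols <- which(is_match)
  for (j in seq_len(L)) {
    col <- colmat[, mcols[j]]
    col <- col[col != "-"]
    cnt <- table(factor(col, levels = AA20))
    p <- (as.numeric(cnt) + alpha * background) / (length(col) + alpha)
    emis[j, ] <- p / sum(p)
  }

  # transitions from per-row state paths; state index 0 is begin
  tc <- matrix(1, nrow = L + 1L, ncol = 7,
               dimnames = list(NULL, c("MM", "MI", "MD", "IM", "II", "DM", "DD")))
  tc[] <- 1  # pseudocount
  add <- function(k, what) tc[k + 1L, what] <<- tc[k + 1L, what] + 1
  for (r in seq_len(nrow_al)) {
    state <- "M"; k <- 0L
    for (c in seq_len(ncol_al)) {
      ch <- colmat[r, c]
      if (is_match[c]) {
        km <- match_idx[c]
        to <- if (ch == "-") "D" else "M"
        add(k, paste0(state, to))
        state <- to; k <- km
      } else if (ch != "-") {
        if (state == "I") add(k, "II") else add(k, paste0(state, "I"))
        state <- "I"
      }
    }
    add(k, paste0(state, "M"))  # to end
  }
  trans <- tc
  trans[, 1:3] <- tc[, 1:3] / rowSums(tc[, 1:3])
  trans[, 4:5] <- tc[, 4:5] / rowSums(tc[, 4:5])
  trans[, 6:7] <- tc[, 6:7] / rowSums(tc[, 6:7])

  member_virus_ids <- if (!is.null(cluster)) {
    sort(unique(cluster$members$genome_id))
  } else character()
  structure(list(
    pphmm_id = if (!is.null(cluster)) cluster$cluster_id else "PPHMM",
    n_match_states = L,
    match_emissions = emis,
    insert_emissions = background,
    transitions = trans,
    background = background,
    member_virus_ids = member_virus_ids,
    member_feature_ids = if (!is.null(cluster)) cluster$members$feature_id
    else character()),
    class = "cgj_pphmm")
}

#' Build the PPHMM database for a manifest
#'
#' Runs all-vs-all similarity over the pooled proteins of the selected
#' genomes, clusters them, aligns each cluster and turns each alignment
#' into a profile HMM. The resulting ordered database defines the
#' column order of every downstream signature.
#'
#' @param manifest A `cgj_manifest`.
#' @param scoring A [scoring_system()].
#' @param threshold Clustering bit-score threshold.
#' @param method Clustering method (see [cluster_proteins()]).
#' @param alpha Emission pseudocount strength.
#' @param classified_only Use only classified genomes (the reference
#'   set) to build the database.
#' @param edges Optional precomputed edge list (e.g. from
#'   [import_similarity_scores()]); skips the internal all-vs-all.
#' @return An object of class `cgj_pphmm_db` with elements `pphmms`
#'   (named ordered list) and `provenance`.
#' @export
build_pphmm_database <- function(manifest, scoring = scoring_system(),
                                 threshold = 30,
                                 method = c("components", "mcl_like"),
                                 alpha = 1, classified_only = TRUE,
                                 edges = NULL) {
  method <- match.arg(method)
  genomes <- if (classified_only) {
    manifest$genomes[manifest$classified]
  } else manifest$genomes
  if (!length(genomes)) stop("no genomes selected for database build")
  proteins <- do.call(rbind, c(lapply(genomes, function(g) g$features),
                               list(make.row.names = FALSE)))
  if (is.null(edges)) {
    edges <- pairwise_similarity(proteins, scoring, min_score = threshold)
  }
  clusters <- cluster_proteins(edges, proteins, method = method,
                               threshold = threshold)
  pphmms <- lapply(clusters, function(cl) {
    build_pphmm(align_cluster(cl, proteins, scoring), cl, alpha = alpha)
  })
  names(pphmms) <- vapply(pphmms, function(p) p$pphmm_id, character(1))
  structure(list(pphmms = pphmms,
                 provenance = list(threshold = threshold, method = method,
                                   alpha = alpha,
                                   n_proteins = nrow(proteins))),
            class = "cgj_pphmm_db")
}

#' @export
print.cgj_pphmm_db <- function(x, ...) {
  cat(sprintf("<cgj_pphmm_db> %d PPHMMs (clustering %s, threshold %g bits)\n",
              length(x$pphmms), x$provenance$method, x$provenance$threshold))
  invisible(x)
}

#' Drop single-virus PPHMMs from well-sampled families
#'
#' Removes each PPHMM whose members come from a single virus when that
#' virus belongs to a family represented by more than two viruses in the
#' manifest: in a well-sampled family a gene seen in one member only
#' carries no grouping signal. Single-virus PPHMMs of unclassified
#' viruses or of families with at most two members are retained.
#'
#' @param db A `cgj_pphmm_db`.
#' @param manifest Manifest carrying family labels.
#' @return Filtered `cgj_pphmm_db` (idempotent).
#' @export
filter_singletons <- function(db, manifest) {
  fams <- vapply(manifest$genomes, function(g) g$taxonomy[["family"]],
                 character(1))
  fam_sizes <- table(fams[nzchar(fams)])
  keep <- vapply(db$pphmms, function(p) {
    if (length(p$member_virus_ids) != 1L) return(TRUE)
    v <- p$member_virus_ids
    fam <- if (v %in% names(fams)) fams[[v]] else ""
    if (!nzchar(fam)) return(TRUE)
    fam_sizes[[fam]] <= 2
  }, logical(1))
  db$pphmms <- db$pphmms[keep]
  db
}

aa_codes <- function(s) {
  match(strsplit(s, "")[[1]], AA20) - 1L  # NA -> skipped by the kernel
}

#' Forward-algorithm bit score of a protein against one PPHMM
#'
#' Sums over all alignments of the sequence to the model (forward
#' algorithm in log space) and reports the log-odds against the
#' background null in bits. Residues outside the 20 standard amino
#' acids are skipped.
#'
#' @param pphmm A `cgj_pphmm`.
#' @param sequence Amino-acid string.
#' @return Bit score (may be negative).
#' @export
forward_bits <- function(pphmm, sequence) {
  codes <- aa_codes(sequence)
  codes[is.na(codes)] <- -1L
  lo <- forward_logodds_cpp(
    log(pphmm$match_emissions) - rep(log(pphmm$background),
                                     each = nrow(pphmm$match_emissions)),
    log(pphmm$transitions), codes)
  lo / log(2)
}

#' Scan a genome's proteins against a PPHMM database
#'
#' Every protein is scored against every PPHMM with [forward_bits()];
#' per PPHMM the best-scoring protein is kept as the hit when its score
#' exceeds `score_floor`. The hit midpoint is the fractional position of
#' the feature's midpoint in the genome's concatenated coordinates.
#'
#' @param genome An `annotated_genome()`.
#' @param db A `cgj_pphmm_db`.
#' @param score_floor Minimum bit score for a hit (strictly exceeded).
#' @return Data frame of hits: `genome_id`, `pphmm_id`, `score`,
#'   `midpoint`, `strand`, `feature_id` (at most one row per PPHMM).
#' @export
scan_genome <- function(genome, db, score_floor = 0) {
  if (!length(db$pphmms)) stop("empty PPHMM database")
  f <- genome$features
  empty <- data.frame(genome_id = character(), pphmm_id = character(),
                      score = numeric(), midpoint = numeric(),
                      strand = character(), feature_id = character(),
                      stringsAsFactors = FALSE)
  if (nrow(f) == 0L) return(empty)
  mids <- feature_midpoints(genome)
  codes <- lapply(f$translation, function(s) {
    x <- aa_codes(s); x[is.na(x)] <- -1L; x
  })
  hits <- vector("list", length(db$pphmms))
  for (pi in seq_along(db$pphmms)) {
    p <- db$pphmms[[pi]]
    lodds <- log(p$match_emissions) -
      rep(log(p$background), each = nrow(p$match_emissions))
    ltr <- log(p$transitions)
    scores <- vapply(codes, function(x)
      forward_logodds_cpp(lodds, ltr, x) / log(2), numeric(1))
    best <- which.max(scores)
    if (scores[best] > score_floor) {
      hits[[pi]] <- data.frame(
        genome_id = genome$genome_id, pphmm_id = p$pphmm_id,
        score = scores[best], midpoint = mids[best],
        strand = f$strand[best], feature_id = f$feature_id[best],
        stringsAsFactors = FALSE)
    }
  }
  hits <- hits[!vapply(hits, is.null, logical(1))]
  if (!length(hits)) return(empty)
  do.call(rbind, c(hits, list(make.row.names = FALSE)))
}

#' Export a PPHMM database in HMMER3 ASCII format
#'
#' Writes match emissions, insert emissions and state transitions of
#' each model as a minimal HMMER3/f text profile for interoperability;
#' scores produced by HMMER on these files use HMMER's own calibration.
#'
#' @param db A `cgj_pphmm_db`.
#' @param path Output file.
#' @export
write_hmmer3 <- function(db, path) {
  con <- file(path, "w")
  on.exit(close(con))
  fmt <- function(p) ifelse(p <= 0, "*", sprintf("%.5f", -log(p)))
  for (p in db$pphmms) {
    writeLines(c(sprintf("HMMER3/f [cgjtax export]"),
                 sprintf("NAME  %s", p$pphmm_id),
                 sprintf("LENG  %d", p$n_match_states),
                 "ALPH  amino",
                 paste0("HMM            ", paste(AA20, collapse = "        ")),
                 paste("           m->m     m->i     m->d     i->m",
                       "    i->i     d->m     d->d")), con)
    writeLines(paste0("  COMPO ", paste(fmt(p$background), collapse = " ")), con)
    writeLines(paste0("        ", paste(fmt(p$insert_emissions), collapse = " ")), con)
    writeLines(paste0("        ", paste(fmt(p$transitions[1, ]), collapse = " ")), con)
    for (k in seq_len(p$n_match_states)) {
      writeLines(paste0(sprintf("%7d ", k),
                        paste(fmt(p$match_emissions[k, ]), collapse = " ")), con)
      writeLines(paste0("        ", paste(fmt(p$insert_emissions), collapse = " ")), con)
      writeLines(paste0("        ", paste(fmt(p$transitions[k + 1L, ]), collapse = " ")), con)
    }
    writeLines("//", con)
  }
  invisible(NULL)
}
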