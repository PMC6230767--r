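# Reading annotated genomes and taxonomy metadata; tabular output.
#
# Genomes are represented as plain R lists (S3 class "cgj_genome"):
#   genome_id        unique id within a dataset (defaults to the accession)
#   accession        primary accession
#   segment_lengths  integer vector, one entry per segment (nt)
#   segment_seqs     character vector of nucleotide sequences ("" if absent)
#   features         data.frame: feature_id, genome_id, segment_index
#                    (0-based), start, end (1-based inclusive), strand
#                    ("+"/"-"), translation
#   taxonomy         named character vector over METADATA_FIELDS
# A dataset manifest (S3 "cgj_manifest") bundles a named list of genomes
# with a per-genome classified flag.

#' Metadata columns expected in the taxonomy TSV
#'
#' The ten per-genome metadata fields: Baltimore classification group,
#' order, family, subfamily, genus, virus name, GenBank accession,
#' RefSeq accession, description and host group.
#'
#' @export
METADATA_FIELDS <- c("baltimore_group", "order", "family", "subfamily",
                     "genus", "virus_name", "genbank_accession",
                     "refseq_accession", "description", "host_group")

empty_taxonomy <- function() {
  stats::setNames(rep("", length(METADATA_FIELDS)), METADATA_FIELDS)
}

#' Construct an annotated genome
#'
#' @param genome_id Unique genome identifier.
#' @param accession Primary accession (defaults to `genome_id`).
#' @param segment_lengths Integer vector of segment lengths in nt.
#' @param segment_seqs Optional character vector of nucleotide sequences,
#'   parallel to `segment_lengths`.
#' @param features Data frame of CDS features with columns `feature_id`,
#'   `segment_index` (0-based), `start`, `end` (1-based inclusive),
#'   `strand` (`"+"`/`"-"`) and `translation`.
#' @param taxonomy Named character vector over [METADATA_FIELDS]; missing
#'   entries default to `""`.
#' @return An object of class `cgj_genome`.
#' @export
annotated_genome <- function(genome_id, accession = genome_id,
                             segment_lengths, segment_seqs = NULL,
                             features, taxonomy = empty_taxonomy()) {
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  need <- c("feature_id", "segment_index", "start", "end", "strand",
            "translation")
  if (!all(need %in% names(features))) {
    stop("features must have columns: ", paste(need, collapse = ", "))
  }
  features$genome_id <- rep(genome_id, nrow(features))
  if (is.null(segment_seqs)) segment_seqs <- rep("", length(segment_lengths))
  tx <- empty_taxonomy()
  tx[intersect(names(taxonomy), METADATA_FIELDS)] <-
    taxonomy[intersect(names(taxonomy), METADATA_FIELDS)]
  g <- structure(list(genome_id = genome_id, accession = accession,
                      segment_lengths = as.integer(segment_lengths),
                      segment_seqs = as.character(segment_seqs),
                      features = features, taxonomy = tx),
                 class = "cgj_genome")
  validate_genome(g)
  g
}

validate_genome <- function(g) {
  f <- g$features
  if (nrow(f)) {
    stopifnot_named(
      "feature start must be <= end" = all(f$start <= f$end),
      "feature strand must be '+' or '-'" = all(f$strand %in% c("+", "-")),
      "feature translation must be non-empty" = all(nchar(f$translation) >= 1),
      "feature segment_index out of range" =
        all(f$segment_index >= 0 & f$segment_index < length(g$segment_lengths)),
      "feature coordinates exceed segment length" =
        all(f$end <= g$segment_lengths[f$segment_index + 1L])
    )
    if (any(grepl("\\*", sub("\\*$", "", f$translation)))) {
      stop("internal stop codon in translation of genome ", g$genome_id)
    }
  }
  invisible(g)
}

#' Bundle genomes into a dataset manifest
#'
#' @param genomes List of [annotated_genome()] objects.
#' @param classified Logical vector (recycled) flagging genomes with
#'   taxonomic assignments; genomes lacking metadata are unclassified.
#' @return An object of class `cgj_manifest` with elements `genomes`
#'   (named list) and `classified` (named logical).
#' @export
dataset_manifest <- function(genomes, classified = TRUE) {
  if (length(genomes) == 0L) stop("manifest needs at least one genome")
  ids <- vapply(genomes, function(g) g$genome_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate genome_id in manifest: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  names(genomes) <- ids
  classified <- rep_len(as.logical(classified), length(genomes))
  names(classified) <- ids
  structure(list(genomes = genomes, classified = classified),
            class = "cgj_manifest")
}

#' @export
print.cgj_manifest <- function(x, ...) {
  cat(sprintf("<cgj_manifest> %d genomes (%d classified), %d CDS features\n",
              length(x$genomes), sum(x$classified),
              nrow(manifest_proteins(x))))
  invisible(x)
}

#' Extract all protein-coding features of a manifest
#'
#' Pools the CDS features of every genome (all segments) into one data
#' frame; `feature_id` values are unique across the dataset.
#'
#' @param manifest A `cgj_manifest`.
#' @return Data frame with one row per CDS feature.
#' @export
manifest_proteins <- function(manifest) {
  do.call(rbind, c(lapply(manifest$genomes, function(g) g$features),
                   list(make.row.names = FALSE)))
}

# Fractional midpoint of a feature in the concatenated-coordinate system
# of its genome: segments are laid end to end in segment order.
feature_midpoints <- function(genome) {
  f <- genome$features
  offs <- c(0, cumsum(as.numeric(genome$segment_lengths)))
  total <- offs[length(offs)]
  (offs[f$segment_index + 1L] + (f$start + f$end) / 2) / total
}

## ---------------------------------------------------------------------
## GenBank flat files

#' Read GenBank flat files into a dataset manifest
#'
#' Each LOCUS record becomes one genome; only CDS features are used.
#' CDS lacking a `/translation` qualifier are translated from the
#' nucleotide sequence (reverse-complemented for minus-strand features)
#' with translation table 11 unless the feature carries `/transl_table`.
#' A trailing stop is stripped; an internal stop triggers a warning and
#' the feature is kept with stops removed.
#'
#' @param paths Character vector of GenBank file paths.
#' @param transl_table Default genetic code table (NCBI numbering).
#' @return A `cgj_manifest`; all genomes are initially flagged
#'   unclassified until [read_metadata()] attaches taxonomy.
#' @export
read_genbank <- function(paths, transl_table = 11L) {
  genomes <- list()
  for (path in paths) {
    if (!file.exists(path)) stop("file not found: ", path)
    lines <- readLines(path, warn = FALSE)
    starts <- grep("^LOCUS ", lines)
    if (length(starts) == 0L) stop("no LOCUS record in ", path)
    ends <- grep("^//\\s*$", lines)
    if (length(ends) < length(starts)) {
      stop("malformed GenBank file (unterminated record): ", path)
    }
    for (i in seq_along(starts)) {
      rec <- lines[starts[i]:ends[i]]
      g <- tryCatch(parse_genbank_record(rec, transl_table),
                    error = function(e) {
                      stop("malformed record ", i, " in ", path, ": ",
                           conditionMessage(e), call. = FALSE)
                    })
      genomes[[length(genomes) + 1L]] <- g
    }
  }
  dataset_manifest(genomes, classified = FALSE)
}

parse_genbank_record <- function(rec, transl_table) {
  locus_tok <- strsplit(trimws(rec[1]), "\\s+")[[1]]
  locus_name <- locus_tok[2]
  seg_len <- suppressWarnings(as.integer(locus_tok[3]))
  acc_line <- grep("^ACCESSION", rec, value = TRUE)
  accession <- if (length(acc_line)) {
    strsplit(trimws(sub("^ACCESSION", "", acc_line[1])), "\\s+")[[1]][1]
  } else locus_name
  if (is.na(accession) || !nzchar(accession)) accession <- locus_name

  feat_from <- grep("^FEATURES", rec)
  origin_at <- grep("^ORIGIN", rec)
  seq <- ""
  if (length(origin_at)) {
    body <- rec[(origin_at[1] + 1L):(length(rec) - 1L)]
    seq <- toupper(gsub("[^A-Za-z]", "", paste(body, collapse = "")))
  }
  if (is.na(seg_len)) seg_len <- nchar(seq)
  if (nzchar(seq) && nchar(seq) != seg_len) {
    stop("sequence length disagrees with LOCUS length for ", locus_name)
  }

  feats <- list()
  if (length(feat_from)) {
    fend <- if (length(origin_at)) origin_at[1] - 1L else length(rec) - 1L
    ftab <- rec[(feat_from[1] + 1L):fend]
    # feature keys start at column 6; qualifier/continuation lines at 22
    key_at <- grep("^ {5}\\S", ftab)
    for (k in seq_along(key_at)) {
      blk <- ftab[key_at[k]:(if (k < length(key_at)) key_at[k + 1L] - 1L
                             else length(ftab))]
      key <- strsplit(trimws(blk[1]), "\\s+")[[1]][1]
      if (key != "CDS") next
      feats[[length(feats) + 1L]] <- parse_cds_block(blk, seq, transl_table,
                                                     accession)
    }
  }
  features <- if (length(feats)) {
    do.call(rbind, c(feats, list(make.row.names = FALSE)))
  } else {
    data.frame(feature_id = character(), segment_index = integer(),
               start = integer(), end = integer(), strand = character(),
               translation = character(), stringsAsFactors = FALSE)
  }
  if (nrow(features)) {
    features$feature_id <- sprintf("%s.cds%d", accession,
                                   seq_len(nrow(features)))
    features$segment_index <- 0L
  }
  annotated_genome(genome_id = accession, accession = accession,
                   segment_lengths = seg_len, segment_seqs = seq,
                   features = features)
}

parse_cds_block <- function(blk, seq, transl_table, accession) {
  # fold continuation lines of the location (lines before first qualifier)
  qual_at <- grep("^ {21}/", blk)
  loc_end <- if (length(qual_at)) qual_at[1] - 1L else length(blk)
  loc <- gsub("\\s+", "", paste(sub("^ {5}\\S+\\s*", "", blk[1]),
                                paste(trimws(blk[seq_len(loc_end)[-1]]),
                                      collapse = ""), sep = ""))
  p <- parse_location(loc)

  quals <- parse_qualifiers(blk[qual_at[1]:length(blk)], exists = length(qual_at) > 0)
  tt <- if (!is.null(quals$transl_table)) as.integer(quals$transl_table) else transl_table
  translation <- quals$translation
  if (is.null(translation)) {
    if (!nzchar(seq)) stop("CDS without /translation and no sequence")
    cds_nt <- paste(vapply(seq_len(nrow(p$parts)), function(j) {
      substr(seq, p$parts$start[j], p$parts$end[j])
    }, character(1)), collapse = "")
    dna <- Biostrings::DNAString(cds_nt)
    if (p$strand == "-") dna <- Biostrings::reverseComplement(dna)
    n_codon <- floor(length(dna) / 3)
    dna <- Biostrings::subseq(dna, 1L, n_codon * 3L)
    translation <- as.character(Biostrings::translate(
      dna, genetic.code = Biostrings::getGeneticCode(as.character(tt)),
      if.fuzzy.codon = "X"))
    translation <- sub("\\*$", "", translation)
  }
  if (grepl("\\*", translation)) {
    warning("internal stop codon in CDS of ", accession,
            "; stops stripped", call. = FALSE)
    translation <- gsub("\\*", "", translation)
  }
  data.frame(feature_id = NA_character_, segment_index = 0L,
             start = min(p$parts$start), end = max(p$parts$end),
             strand = p$strand, translation = translation,
             stringsAsFactors = FALSE)
}

# Supports `a..b`, `complement(...)`, `join(a..b,c..d)` and partial
# markers (< >); returns strand plus the part table.
parse_location <- function(loc) {
  strand <- "+"
  x <- loc
  if (grepl("^complement\\(", x)) {
    strand <- "-"
    x <- sub("^complement\\((.*)\\)$", "\\1", x)
  }
  if (grepl("^join\\(", x)) x <- sub("^join\\((.*)\\)$", "\\1", x)
  parts <- strsplit(x, ",")[[1]]
  tab <- lapply(parts, function(p) {
    p <- gsub("[<>]", "", p)
    if (grepl("^complement\\(", p)) {
      strand <<- "-"
      p <- sub("^complement\\((.*)\\)$", "\\1", p)
    }
    nums <- as.integer(strsplit(p, "\\.\\.")[[1]])
    if (any(is.na(nums))) stop("unparseable location: ", loc)
    data.frame(start = nums[1], end = nums[length(nums)])
  })
  list(strand = strand, parts = do.call(rbind, tab))
}

parse_qualifiers <- function(lines, exists = TRUE) {
  out <- list()
  if (!exists) return(out)
  cur_key <- NULL
  cur_val <- NULL
  flush <- function() {
    if (!is.null(cur_key)) {
      v <- gsub("^\"|\"$", "", cur_val)
      out[[cur_key]] <<- v
    }
  }
  for (ln in lines) {
    t <- trimws(ln)
    if (startsWith(t, "/")) {
      flush()
      eq <- regexpr("=", t, fixed = TRUE)
      if (eq > 0) {
        cur_key <- substr(t, 2L, eq - 1L)
        cur_val <- substr(t, eq + 1L, nchar(t))
      } else {
        cur_key <- substr(t, 2L, nchar(t))
        cur_val <- "TRUE"
      }
    } else if (!is.null(cur_key)) {
      # translations continue without separators; free text keeps a space
      sep <- if (cur_key == "translation") "" else " "
      cur_val <- paste(cur_val, t, sep = sep)
    }
  }
  flush()
  out
}

## ---------------------------------------------------------------------
## FASTA + GFF3

#' Read genomes from FASTA plus GFF3 feature tables
#'
#' One genome per FASTA record. CDS features are taken from the GFF3;
#' a `translation` attribute is used when present, otherwise the CDS is
#' translated from the sequence with `transl_table`.
#'
#' @param fasta_path Nucleotide FASTA.
#' @param gff_path GFF3 with CDS features whose `seqid` matches the
#'   FASTA record names.
#' @param transl_table Genetic code table (NCBI numbering).
#' @return A `cgj_manifest` (all genomes unclassified until metadata is
#'   attached).
#' @export
read_fasta_gff <- function(fasta_path, gff_path, transl_table = 11L) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("reading GFF3 requires the rtracklayer package")
  }
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  gr <- rtracklayer::import(gff_path, format = "gff3")
  gr <- gr[as.character(gr$type) == "CDS"]
  genomes <- lapply(names(seqs), function(id) {
    seq <- as.character(seqs[[id]])
    sub <- gr[as.character(GenomicRanges::seqnames(gr)) == id]
    n <- length(sub)
    translation <- character(n)
    has_tr <- if (!is.null(sub$translation)) !is.na(sub$translation) else rep(FALSE, n)
    for (j in seq_len(n)) {
      if (has_tr[j]) {
        translation[j] <- as.character(sub$translation[j])
      } else {
        nt <- substr(seq, GenomicRanges::start(sub)[j], GenomicRanges::end(sub)[j])
        dna <- Biostrings::DNAString(nt)
        if (as.character(GenomicRanges::strand(sub))[j] == "-") {
          dna <- Biostrings::reverseComplement(dna)
        }
        dna <- Biostrings::subseq(dna, 1L, 3L * floor(length(dna) / 3))
        translation[j] <- sub("\\*$", "", as.character(Biostrings::translate(
          dna,
          genetic.code = Biostrings::getGeneticCode(as.character(transl_table)))))
      }
    }
    feats <- data.frame(
      feature_id = sprintf("%s.cds%d", id, seq_len(n)),
      segment_index = 0L,
      start = GenomicRanges::start(sub), end = GenomicRanges::end(sub),
      strand = ifelse(as.character(GenomicRanges::strand(sub)) == "-", "-", "+"),
      translation = translation, stringsAsFactors = FALSE)
    annotated_genome(genome_id = id, segment_lengths = nchar(seq),
                     segment_seqs = seq, features = feats)
  })
  dataset_manifest(genomes, classified = FALSE)
}

## ---------------------------------------------------------------------
## Metadata

#' Attach taxonomy metadata to a manifest
#'
#' Matches metadata rows to genomes by GenBank accession. A row whose
#' `genbank_accession` cell lists several accessions separated by `;`
#' joins those records into one multi-segment genome (segments in the
#' listed order, proteins pooled). Genomes without a metadata row are
#' flagged unclassified.
#'
#' @param path TSV file whose header contains the ten [METADATA_FIELDS].
#' @param manifest A `cgj_manifest` from [read_genbank()] or
#'   [read_fasta_gff()].
#' @return The manifest with taxonomy attached and classified flags set.
#' @export
read_metadata <- function(path, manifest) {
  md <- utils::read.delim(path, colClasses = "character",
                          check.names = FALSE)
  missing_cols <- setdiff(METADATA_FIELDS, names(md))
  if (length(missing_cols)) {
    stop("metadata TSV lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(md$genbank_accession)) {
    stop("duplicate accession rows in metadata: ",
         paste(unique(md$genbank_accession[duplicated(md$genbank_accession)]),
               collapse = ", "))
  }
  genomes <- manifest$genomes
  acc_of <- vapply(genomes, function(g) g$accession, character(1))
  classified <- stats::setNames(rep(FALSE, length(genomes)), names(genomes))
  out <- genomes
  drop <- character()
  for (r in seq_len(nrow(md))) {
    accs <- trimws(strsplit(md$genbank_accession[r], ";")[[1]])
    hit <- names(genomes)[match(accs, acc_of)]
    if (anyNA(hit)) {
      warning("metadata row ", r, " (", md$genbank_accession[r],
              ") matches no genome", call. = FALSE)
      next
    }
    tx <- stats::setNames(as.character(md[r, METADATA_FIELDS]),
                          METADATA_FIELDS)
    if (length(hit) > 1L) {
      joined <- join_segments(genomes[hit], tx)
      out[[hit[1]]] <- joined
      drop <- c(drop, hit[-1])
      classified[hit[1]] <- TRUE
    } else {
      g <- out[[hit]]
      g$taxonomy <- tx
      out[[hit]] <- g
      classified[hit] <- TRUE
    }
  }
  keep <- setdiff(names(out), drop)
  dataset_manifest(out[keep], classified = classified[keep])
}

# Merge single-segment genomes into one multi-segment genome, renaming
# features and re-indexing segments in the given order.
join_segments <- function(glist, taxonomy) {
  id <- glist[[1]]$genome_id
  seg_lengths <- unlist(lapply(glist, function(g) g$segment_lengths))
  seg_seqs <- unlist(lapply(glist, function(g) g$segment_seqs))
  feats <- list()
  offset <- 0L
  for (g in glist) {
    f <- g$features
    if (nrow(f)) {
      f$segment_index <- f$segment_index + offset
      f$genome_id <- id
      feats[[length(feats) + 1L]] <- f
    }
    offset <- offset + length(g$segment_lengths)
  }
  features <- if (length(feats)) do.call(rbind, feats) else glist[[1]]$features
  annotated_genome(genome_id = id, accession = glist[[1]]$accession,
                   segment_lengths = seg_lengths, segment_seqs = seg_seqs,
                   features = features, taxonomy = taxonomy)
}

## ---------------------------------------------------------------------
## Tabular output

#' Write a labelled numeric table as TSV
#'
#' Values are written with 12 significant digits so a write/read cycle
#' reproduces them to within 1e-9 relative error.
#'
#' @param x Matrix or data frame; numeric entries must be finite.
#' @param path Output path.
#' @param kind One of `"signatures"`, `"distances"`, `"clusters"`, `"mi"`
#'   (recorded as a comment line for provenance).
#' @export
write_table <- function(x, path,
                        kind = c("signatures", "distances", "clusters", "mi")) {
  kind <- match.arg(kind)
  if (is.matrix(x)) {
    if (any(!is.finite(x))) stop("non-finite value in table of kind ", kind)
    chr <- matrix(formatC(x, digits = 12, format = "g"), nrow(x), ncol(x))
    df <- data.frame(id = if (is.null(rownames(x))) as.character(seq_len(nrow(x)))
                     else rownames(x),
                     as.data.frame(chr, stringsAsFactors = FALSE),
                     check.names = FALSE, stringsAsFactors = FALSE)
    colnames(df) <- c("id", colnames(x))
  } else {
    df <- as.data.frame(x)
    num <- vapply(df, is.numeric, logical(1))
    if (any(vapply(df[num], function(v) any(!is.finite(v)), logical(1)))) {
      stop("non-finite value in table of kind ", kind)
    }
    df[num] <- lapply(df[num], formatC, digits = 12, format = "g")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# cgjtax table kind=", kind), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' Read back a numeric matrix written by [write_table()]
#'
#' @param path TSV path.
#' @return Numeric matrix with row names from the `id` column.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          colClasses = "character")
  if (nrow(df) == 0L) {
    m <- matrix(numeric(), 0, ncol(df) - 1L)
    colnames(m) <- setdiff(names(df), "id")
    return(m)
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df$id
  m
}
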