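# Synthetic annotated virus genomes with known family/genus structure,
# tunable divergence, synteny conservation, gene loss and mosaicism.
# Everything downstream of genome reading can be exercised on these
# datasets without any sequence download.

# Most-frequent codon per amino acid (translation table 11 hosts,
# E. coli usage); used for back-translation of simulated proteins.
PREFERRED_CODON <- c(
  A = "GCG", R = "CGC", N = "AAC", D = "GAT", C = "TGC", Q = "CAG",
  E = "GAA", G = "GGC", H = "CAT", I = "ATT", L = "CTG", K = "AAA",
  M = "ATG", F = "TTT", P = "CCG", S = "AGC", T = "ACC", W = "TGG",
  Y = "TAT", V = "GTG")

#' Simulation configuration
#'
#' Defaults describe a set of cohesive virus families: moderately
#' divergent members (15% of residues substituted relative to the
#' family ancestor), occasional whole-gene loss and strand inversion,
#' and no gene sharing across families.
#'
#' @param n_families Number of families to found.
#' @param members_per_family Genomes per family.
#' @param genes_per_family Genes in each family's ancestor.
#' @param gene_length_range Min/max ancestor gene length (aa).
#' @param substitution_rate Expected fraction of residues substituted
#'   per member relative to the ancestor.
#' @param gene_loss_prob Per-gene probability a member loses the gene
#'   (at least one gene is always retained).
#' @param inversion_prob Per-gene probability the member carries the
#'   gene on the opposite strand.
#' @param shared_gene_fraction Fraction of each family's genes drawn
#'   from a common cross-family pool (mosaicism).
#' @param genera_per_family Number of genus labels each family's
#'   members are split into.
#' @param intergenic_range Min/max intergenic spacer length (nt).
#' @param seed RNG seed; the whole dataset is a deterministic function
#'   of the configuration.
#' @return A list of class `cgj_sim_config`.
#' @export
sim_config <- function(n_families = 5, members_per_family = 6,
                       genes_per_family = 6,
                       gene_length_range = c(60, 120),
                       substitution_rate = 0.15, gene_loss_prob = 0.1,
                       inversion_prob = 0.05, shared_gene_fraction = 0,
                       genera_per_family = 1,
                       intergenic_range = c(20, 60), seed = 1) {
  cfg <- list(n_families = n_families,
              members_per_family = members_per_family,
              genes_per_family = genes_per_family,
              gene_length_range = gene_length_range,
              substitution_rate = substitution_rate,
              gene_loss_prob = gene_loss_prob,
              inversion_prob = inversion_prob,
              shared_gene_fraction = shared_gene_fraction,
              genera_per_family = genera_per_family,
              intergenic_range = intergenic_range, seed = seed)
  probs <- c("substitution_rate", "gene_loss_prob", "inversion_prob",
             "shared_gene_fraction")
  for (p in probs) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) stop(p, " must lie in [0, 1]")
  }
  if (n_families < 1 || members_per_family < 1 || genes_per_family < 1) {
    stop("counts must be at least 1")
  }
  structure(cfg, class = "cgj_sim_config")
}

random_protein <- function(len) {
  paste0("M", paste(sample(AA20, len - 1L, replace = TRUE), collapse = ""))
}

substitute_protein <- function(seq, rate) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(chars)) < rate)
  for (i in hit) {
    chars[i] <- sample(setdiff(AA20, chars[i]), 1L)
  }
  paste(chars, collapse = "")
}

back_translate <- function(protein) {
  paste0(paste(PREFERRED_CODON[strsplit(protein, "")[[1]]], collapse = ""),
         "TAA")
}

revcomp <- function(nt) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(nt)))
}

#' Simulate annotated genomes with known family structure
#'
#' Per family an ancestor is drawn: an ordered set of random protein
#' genes with strands and intergenic spacers. Each member genome then
#' applies residue substitutions at the configured rate, whole-gene
#' loss and strand inversions, and the proteins are back-translated to
#' nucleotide CDS. Valid GenBank flat files, a metadata TSV and a truth
#' table are written to `dir`.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @param family_prefix,host_group,baltimore_group Labels recorded in
#'   the metadata.
#' @return List with `manifest` (the dataset re-read through
#'   [read_genbank()] and [read_metadata()]), `truth` (data frame
#'   genome_id/family/genus), `gene_truth` (gene_id/founding_family),
#'   `genome_paths`, `metadata_path`.
#' @export
simulate_genomes <- function(config, dir = tempfile("simgen"),
                             family_prefix = "FAM",
                             host_group = "bacteria",
                             baltimore_group = "I") {
  stopifnot(inherits(config, "cgj_sim_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  built <- with_rng_seed(config$seed,
                         draw_dataset(config, family_prefix))
  write_simulated(built, dir, host_group, baltimore_group)
}

draw_dataset <- function(config, family_prefix) {
  fams <- sprintf("%s%02d", family_prefix, seq_len(config$n_families))
  glr <- config$gene_length_range
  # family ancestors
  ancestors <- lapply(fams, function(fam) {
    ng <- config$genes_per_family
    lens <- sample(seq(glr[1], glr[2]), ng, replace = TRUE)
    list(fam = fam,
         genes = vapply(lens, random_protein, character(1)),
         strands = sample(c("+", "-"), ng, replace = TRUE,
                          prob = c(0.75, 0.25)),
         gene_ids = sprintf("%s_gene%02d", fam, seq_len(ng)))
  })
  names(ancestors) <- fams
  # mosaicism: overwrite a fraction of each family's slots from a
  # common pool so the same gene is found across families
  n_shared <- round(config$shared_gene_fraction * config$genes_per_family)
  if (n_shared > 0) {
    pool_lens <- sample(seq(glr[1], glr[2]), n_shared, replace = TRUE)
    pool <- vapply(pool_lens, random_protein, character(1))
    for (fam in fams) {
      slots <- sample.int(config$genes_per_family, n_shared)
      ancestors[[fam]]$genes[slots] <- pool
      ancestors[[fam]]$gene_ids[slots] <-
        sprintf("SHARED_gene%02d", seq_len(n_shared))
    }
  }
  gene_truth <- do.call(rbind, lapply(ancestors, function(a) {
    data.frame(gene_id = a$gene_ids,
               founding_family = ifelse(startsWith(a$gene_ids, "SHARED"),
                                        "shared", a$fam),
               stringsAsFactors = FALSE)
  }))
  gene_truth <- unique(gene_truth)
  rownames(gene_truth) <- NULL

  genomes <- list()
  truth <- list()
  for (fam in fams) {
    anc <- ancestors[[fam]]
    genus_of <- rep(seq_len(config$genera_per_family),
                    length.out = config$members_per_family)
    genus_of <- sort(genus_of)
    for (m in seq_len(config$members_per_family)) {
      gid <- sprintf("%s_V%02d", fam, m)
      ng <- config$genes_per_family
      kept <- which(stats::runif(ng) >= config$gene_loss_prob)
      if (!length(kept)) kept <- sample.int(ng, 1L)
      prots <- vapply(anc$genes[kept], substitute_protein, character(1),
                      rate = config$substitution_rate)
      strands <- anc$strands[kept]
      flip <- stats::runif(length(kept)) < config$inversion_prob
      strands[flip] <- ifelse(strands[flip] == "+", "-", "+")
      genomes[[gid]] <- list(
        genome_id = gid, family = fam,
        genus = sprintf("%s_g%d", fam, genus_of[m]),
        proteins = unname(prots), strands = strands,
        gene_ids = anc$gene_ids[kept],
        spacers = sample(seq(config$intergenic_range[1],
                             config$intergenic_range[2]),
                         length(kept) + 1L, replace = TRUE))
      truth[[gid]] <- data.frame(genome_id = gid, family = fam,
                                 genus = genomes[[gid]]$genus,
                                 stringsAsFactors = FALSE)
    }
  }
  # nucleotide assembly needs RNG for spacers -> draw them here too
  for (gid in names(genomes)) {
    g <- genomes[[gid]]
    genomes[[gid]]$spacer_seqs <- vapply(g$spacers, function(len)
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
            collapse = ""), character(1))
  }
  list(genomes = genomes,
       truth = do.call(rbind, c(truth, list(make.row.names = FALSE))),
       gene_truth = gene_truth)
}

assemble_genome_nt <- function(g) {
  parts <- character(0)
  feats <- list()
  pos <- 0L
  for (k in seq_along(g$proteins)) {
    parts <- c(parts, g$spacer_seqs[k])
    pos <- pos + nchar(g$spacer_seqs[k])
    cds <- back_translate(g$proteins[k])
    if (g$strands[k] == "-") cds_nt <- revcomp(cds) else cds_nt <- cds
    feats[[k]] <- data.frame(start = pos + 1L,
                             end = pos + nchar(cds_nt),
                             strand = g$strands[k],
                             translation = g$proteins[k],
                             stringsAsFactors = FALSE)
    parts <- c(parts, cds_nt)
    pos <- pos + nchar(cds_nt)
  }
  parts <- c(parts, g$spacer_seqs[length(g$spacer_seqs)])
  list(seq = paste(parts, collapse = ""), features = do.call(rbind, feats))
}

write_simulated <- function(built, dir, host_group, baltimore_group) {
  genome_paths <- character(0)
  md_rows <- list()
  for (gid in names(built$genomes)) {
    g <- built$genomes[[gid]]
    asm <- assemble_genome_nt(g)
    path <- file.path(dir, paste0(gid, ".gbk"))
    write_genbank_record(gid, asm$seq, asm$features, path,
                         definition = sprintf("Simulated virus %s.", gid))
    genome_paths <- c(genome_paths, path)
    md_rows[[gid]] <- data.frame(
      baltimore_group = baltimore_group, order = "Simulovirales",
      family = g$family, subfamily = "", genus = g$genus,
      virus_name = gid, genbank_accession = gid, refseq_accession = "",
      description = sprintf("Simulated virus %s", gid),
      host_group = host_group, stringsAsFactors = FALSE)
  }
  metadata_path <- file.path(dir, "metadata.tsv")
  utils::write.table(do.call(rbind, c(md_rows, list(make.row.names = FALSE))),
                     metadata_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  truth_path <- file.path(dir, "truth.tsv")
  utils::write.table(built$truth, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  manifest <- read_metadata(metadata_path, read_genbank(genome_paths))
  list(manifest = manifest, truth = built$truth,
       gene_truth = built$gene_truth, genome_paths = genome_paths,
       metadata_path = metadata_path, truth_path = truth_path, dir = dir)
}

#' Write one genome as a GenBank flat file
#'
#' Emits the dialect [read_genbank()] parses: LOCUS/ACCESSION header,
#' CDS features with `/translation`, and an ORIGIN sequence block.
#'
#' @param accession Record accession (also the LOCUS name).
#' @param seq Nucleotide sequence.
#' @param features Data frame with `start`, `end`, `strand`,
#'   `translation`.
#' @param path Output file.
#' @param definition DEFINITION line text.
#' @export
write_genbank_record <- function(accession, seq, features, path,
                                 definition = "Simulated virus genome.") {
  con <- file(path, "w")
  on.exit(close(con))
  n <- nchar(seq)
  writeLines(sprintf(
    "LOCUS       %-16s %d bp    DNA     linear   PHG 01-JAN-2026",
    accession, n), con)
  writeLines(sprintf("DEFINITION  %s", definition), con)
  writeLines(sprintf("ACCESSION   %s", accession), con)
  writeLines(sprintf("VERSION     %s.1", accession), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  writeLines(sprintf("     source          1..%d", n), con)
  for (k in seq_len(nrow(features))) {
    loc <- sprintf("%d..%d", features$start[k], features$end[k])
    if (features$strand[k] == "-") loc <- sprintf("complement(%s)", loc)
    writeLines(sprintf("     CDS             %s", loc), con)
    writeLines(sprintf("                     /codon_start=1"), con)
    writeLines(sprintf("                     /transl_table=11"), con)
    tr <- features$translation[k]
    wrapped <- substring(tr, seq(1, nchar(tr), 44),
                         pmin(seq(1, nchar(tr), 44) + 43, nchar(tr)))
    wrapped[1] <- paste0("/translation=\"", wrapped[1])
    wrapped[length(wrapped)] <- paste0(wrapped[length(wrapped)], "\"")
    for (w in wrapped) writeLines(sprintf("                     %s", w), con)
  }
  writeLines("ORIGIN", con)
  lower <- tolower(seq)
  for (start in seq(1, n, 60)) {
    chunk <- substring(lower, seq(start, min(start + 59, n), 10),
                       pmin(seq(start, min(start + 59, n), 10) + 9, n))
    writeLines(sprintf("%9d %s", start, paste(chunk, collapse = " ")), con)
  }
  writeLines("//", con)
  invisible(path)
}

#' Two-regime benchmark dataset
#'
#' Builds a labelled dataset contrasting two regimes of family
#' cohesion: a "eukaryote-like" block of cohesive families (every
#' member shares the family's gene set, two genus labels per family)
#' and a "phage-like" block in which genera are cohesive but the
#' genera grouped into one family share essentially no genes, so
#' between-genus distances within a family approach 1.
#'
#' @param seed RNG seed.
#' @param dir Output directory.
#' @return As [simulate_genomes()], plus a `block` column in `truth`.
#' @export
two_regime_benchmark <- function(seed = 1, dir = tempfile("tworegime")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  euk_cfg <- sim_config(n_families = 4, members_per_family = 6,
                        genes_per_family = 6, substitution_rate = 0.15,
                        gene_loss_prob = 0.05, inversion_prob = 0.02,
                        genera_per_family = 2, seed = seed)
  euk <- simulate_genomes(euk_cfg, file.path(dir, "euk"),
                          family_prefix = "EUKFAM",
                          host_group = "eukaryote")
  # phage regime: eight independent founders, later paired into four
  # family labels whose two genera share no ancestry
  phg_cfg <- sim_config(n_families = 8, members_per_family = 3,
                        genes_per_family = 6, substitution_rate = 0.15,
                        gene_loss_prob = 0.05, inversion_prob = 0.02,
                        genera_per_family = 1, seed = seed + 1000L)
  phg <- simulate_genomes(phg_cfg, file.path(dir, "phage"),
                          family_prefix = "PHGGEN",
                          host_group = "bacteria")

  # relabel the phage founders: PHGGEN(2k-1), PHGGEN(2k) -> PHGFAM k
  md_e <- utils::read.delim(euk$metadata_path, colClasses = "character")
  md_p <- utils::read.delim(phg$metadata_path, colClasses = "character")
  founder <- as.integer(sub("^PHGGEN(\\d+)_.*$", "\\1", md_p$genbank_accession))
  md_p$genus <- md_p$family
  md_p$family <- sprintf("PHGFAM%02d", (founder + 1L) %/% 2L)
  md <- rbind(md_e, md_p)
  metadata_path <- file.path(dir, "metadata.tsv")
  utils::write.table(md, metadata_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  truth <- rbind(cbind(euk$truth, block = "eukaryote_like"),
                 transform(phg$truth,
                           genus = family,
                           family = sprintf("PHGFAM%02d",
                                            (as.integer(sub("^PHGGEN(\\d+)$",
                                                            "\\1", family)) + 1L)
                                            %/% 2L),
                           block = "phage_like"))
  rownames(truth) <- NULL
  paths <- c(euk$genome_paths, phg$genome_paths)
  manifest <- read_metadata(metadata_path, read_genbank(paths))
  truth_path <- file.path(dir, "truth.tsv")
  utils::write.table(truth, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(manifest = manifest, truth = truth, genome_paths = paths,
       metadata_path = metadata_path, truth_path = truth_path, dir = dir)
}
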