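# In-code fixtures shared across test files. Heavy simulation runs are
# computed once per session and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# A minimal genome built directly in code.
toy_genome <- function(id = "TOY1", translations = c("MHEAGAWGHEE"),
                       strands = "+", family = "Toyviridae",
                       genus = "Alphatoyvirus", len = 1000L) {
  n <- length(translations)
  starts <- seq(10L, by = 200L, length.out = n)
  feats <- data.frame(
    feature_id = sprintf("%s.cds%d", id, seq_len(n)),
    segment_index = 0L,
    start = starts,
    end = starts + nchar(translations) * 3L + 2L,
    strand = rep_len(strands, n),
    translation = translations,
    stringsAsFactors = FALSE)
  annotated_genome(id, segment_lengths = len, features = feats,
                   taxonomy = c(family = family, genus = genus,
                                genbank_accession = id,
                                baltimore_group = "I",
                                host_group = "bacteria"))
}

toy_protein_df <- function(seqs, genome_ids = NULL) {
  ids <- names(seqs)
  if (is.null(ids)) ids <- sprintf("p%02d", seq_along(seqs))
  if (is.null(genome_ids)) genome_ids <- ids
  data.frame(feature_id = ids, genome_id = genome_ids,
             translation = unname(seqs), stringsAsFactors = FALSE)
}

random_aa <- function(len) {
  paste(sample(cgjtax:::AA20, len, replace = TRUE), collapse = "")
}

# --- shared heavy fixtures -------------------------------------------

# Five cohesive families x six members, divergence 15%, no mosaicism:
# full pipeline run with 100-replicate bootstrap.
family_recovery_run <- function() {
  cached("family_recovery", {
    sim <- simulate_genomes(sim_config(n_families = 5,
                                       members_per_family = 6,
                                       substitution_rate = 0.15,
                                       shared_gene_fraction = 0,
                                       seed = 20260923),
                            dir = file.path(tempdir(), "acc5x6"))
    manifest <- sim$manifest
    db <- filter_singletons(build_pphmm_database(manifest), manifest)
    table <- build_signature_table(manifest, db)
    D <- distance_matrix(table)
    tree <- bootstrap_supports(table, n_reps = 100, seed = 11)
    partition <- collapse(tree, 0.8, manifest)
    list(sim = sim, manifest = manifest, db = db, table = table,
         D = D, tree = tree, partition = partition,
         family = sub("_V.*$", "", rownames(D)))
  })
}

two_regime_run <- function() {
  cached("two_regime", {
    tw <- two_regime_benchmark(seed = 20260923,
                               dir = file.path(tempdir(), "accregime"))
    manifest <- tw$manifest
    db <- filter_singletons(build_pphmm_database(manifest), manifest)
    table <- build_signature_table(manifest, db)
    D <- distance_matrix(table)
    truth <- tw$truth
    rownames(truth) <- truth$genome_id
    list(tw = tw, manifest = manifest, table = table, D = D,
         truth = truth)
  })
}

# Small classified reference plus injected unclassified genomes: two
# related novels from an unrelated founder and one gene-free genome.
classification_run <- function() {
  cached("classification", {
    ref <- simulate_genomes(sim_config(n_families = 3,
                                       members_per_family = 4,
                                       seed = 31),
                            dir = file.path(tempdir(), "accref"))
    novel <- simulate_genomes(sim_config(n_families = 1,
                                         members_per_family = 2,
                                         gene_loss_prob = 0,
                                         seed = 32),
                              dir = file.path(tempdir(), "accnovel"),
                              family_prefix = "NOVEL")
    empty_feats <- data.frame(feature_id = character(),
                              segment_index = integer(),
                              start = integer(), end = integer(),
                              strand = character(),
                              translation = character(),
                              stringsAsFactors = FALSE)
    bare <- annotated_genome("NOGENE01", segment_lengths = 500L,
                             features = empty_feats)
    genomes <- c(ref$manifest$genomes, novel$manifest$genomes,
                 list(NOGENE01 = bare))
    classified <- c(rep(TRUE, length(ref$manifest$genomes)),
                    rep(FALSE, length(novel$manifest$genomes) + 1L))
    joint <- dataset_manifest(genomes, classified)
    db <- filter_singletons(
      build_pphmm_database(joint, classified_only = FALSE), joint)
    table <- build_signature_table(joint, db)
    tree <- upgma(distance_matrix(table))
    partition <- collapse(tree, 0.8, joint)
    report <- assign_unclassified(partition, joint, table, db)
    list(joint = joint, db = db, table = table, partition = partition,
         report = report,
         novel_ids = names(novel$manifest$genomes))
  })
}
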