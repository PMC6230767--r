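# End-to-end orchestration: fixed stage order, declarative config,
# reproducible run directories. Each stage is also exposed as a CLI
# subcommand by the exec/cgjtax script.

#' Declarative run configuration
#'
#' Every stage parameter has a default; the configuration is recorded
#' verbatim into the run log so outputs are a pure function of
#' (inputs, config).
#'
#' @param genome_paths GenBank files of the reference (classified)
#'   dataset.
#' @param metadata_path Taxonomy metadata TSV.
#' @param out_dir Output directory for stage artifacts.
#' @param cluster_threshold Bit-score threshold for protein clustering.
#' @param cluster_method `"components"` or `"mcl_like"`.
#' @param alpha Profile-HMM emission pseudocount strength.
#' @param score_floor Hit acceptance floor (bits).
#' @param collapse_threshold Dendrogram collapse height (CGJ distance).
#' @param bootstrap_reps Bootstrap pseudoreplicates.
#' @param mi_reps Mutual-information replicates.
#' @param mi_per_group Genomes sampled per group per MI replicate.
#' @param baltimore_filter Optional Baltimore group label; when set,
#'   only genomes of that group are analysed (one dendrogram per
#'   group).
#' @param seed Seed governing bootstrap and MI subsampling.
#' @return A list of class `cgj_run_config`.
#' @export
run_config <- function(genome_paths = character(), metadata_path = NULL,
                       out_dir = tempfile("cgjrun"),
                       cluster_threshold = 30,
                       cluster_method = "components", alpha = 1,
                       score_floor = 0, collapse_threshold = 0.8,
                       bootstrap_reps = 100, mi_reps = 100,
                       mi_per_group = 2, baltimore_filter = NULL,
                       seed = 1) {
  structure(list(genome_paths = genome_paths,
                 metadata_path = metadata_path, out_dir = out_dir,
                 cluster_threshold = cluster_threshold,
                 cluster_method = cluster_method, alpha = alpha,
                 score_floor = score_floor,
                 collapse_threshold = collapse_threshold,
                 bootstrap_reps = bootstrap_reps, mi_reps = mi_reps,
                 mi_per_group = mi_per_group,
                 baltimore_filter = baltimore_filter, seed = seed),
            class = "cgj_run_config")
}

load_manifest <- function(config, extra_paths = character()) {
  paths <- c(config$genome_paths, extra_paths)
  if (!length(paths)) stop("no genome paths configured")
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop("missing input file(s): ", paste(missing, collapse = ", "))
  }
  manifest <- read_genbank(paths)
  if (!is.null(config$metadata_path)) {
    if (!file.exists(config$metadata_path)) {
      stop("missing metadata file: ", config$metadata_path)
    }
    manifest <- read_metadata(config$metadata_path, manifest)
  }
  if (!is.null(config$baltimore_filter)) {
    bg <- vapply(manifest$genomes,
                 function(g) g$taxonomy[["baltimore_group"]], character(1))
    keep <- !manifest$classified | bg == config$baltimore_filter
    manifest <- dataset_manifest(manifest$genomes[keep],
                                 manifest$classified[keep])
  }
  manifest
}

log_run <- function(config, stage) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  ser <- vapply(names(unclass(config)), function(k)
    sprintf("%s=%s", k, paste(format(config[[k]]), collapse = ",")),
    character(1))
  cat(c(sprintf("stage=%s time=%s", stage,
                format(Sys.time(), "%Y-%m-%dT%H:%M:%S")), ser, ""),
      file = file.path(config$out_dir, "run.log"), sep = "\n",
      append = TRUE)
}

#' Build the PPHMM database and family GOMs
#'
#' @param config A [run_config()].
#' @param manifest Optional preloaded manifest.
#' @param include_unclassified Also cluster the proteins of
#'   unclassified genomes into the database (used by [run_classify()]
#'   so related queries can form candidate UTU clusters); family GOMs
#'   always come from classified genomes only.
#' @return List with `db` (a `cgj_pphmm_db` after singleton filtering),
#'   `goms` and the reference `table` used to derive the GOMs.
#' @export
run_build_db <- function(config, manifest = NULL,
                         include_unclassified = FALSE) {
  log_run(config, "build-db")
  if (is.null(manifest)) manifest <- load_manifest(config)
  db <- build_pphmm_database(manifest, threshold = config$cluster_threshold,
                             method = config$cluster_method,
                             alpha = config$alpha,
                             classified_only = !include_unclassified)
  db <- filter_singletons(db, manifest)
  table <- build_signature_table(manifest, db,
                                 score_floor = config$score_floor)
  goms <- build_family_goms(table$locations, manifest)
  write_hmmer3(db, file.path(config$out_dir, "pphmm_db.hmm"))
  list(db = db, goms = goms, table = table, manifest = manifest)
}

#' Annotate genomes with PPHMM and GOM signatures
#'
#' @param config A [run_config()].
#' @param db_out Output of [run_build_db()]; built on the fly when
#'   `NULL`.
#' @param manifest Optional manifest to annotate (defaults to the
#'   configured inputs).
#' @return The `cgj_signature_table`.
#' @export
run_annotate <- function(config, db_out = NULL, manifest = NULL) {
  log_run(config, "annotate")
  if (is.null(db_out)) db_out <- run_build_db(config, manifest)
  if (is.null(manifest)) manifest <- db_out$manifest
  table <- build_signature_table(manifest, db_out$db, goms = db_out$goms,
                                 score_floor = config$score_floor)
  write_signature_table(table, file.path(config$out_dir, "signatures.tsv"))
  table
}

#' Distances, dendrogram and cluster partition
#'
#' @param config A [run_config()].
#' @param table Signature table from [run_annotate()]; computed when
#'   `NULL`.
#' @param manifest Optional manifest for composition summaries.
#' @return List with `distances`, `tree` (bootstrapped
#'   `cgj_dendrogram`), `partition` and `leaf_order`.
#' @export
run_relate <- function(config, table = NULL, manifest = NULL) {
  log_run(config, "relate")
  if (is.null(table)) {
    db_out <- run_build_db(config, manifest)
    manifest <- db_out$manifest
    table <- run_annotate(config, db_out, manifest)
  }
  D <- distance_matrix(table)
  tree <- bootstrap_supports(table, n_reps = config$bootstrap_reps,
                             seed = config$seed)
  partition <- collapse(tree, config$collapse_threshold, manifest)
  write_table(unclass(D), file.path(config$out_dir, "distances.tsv"),
              kind = "distances")
  write_newick(tree, file.path(config$out_dir, "dendrogram.nwk"))
  memb <- data.frame(
    cluster_id = rep(names(partition$clusters),
                     lengths(partition$clusters)),
    genome_id = unlist(partition$clusters, use.names = FALSE),
    stringsAsFactors = FALSE)
  if (!is.null(manifest)) {
    memb$classified_flag <- manifest$classified[memb$genome_id]
    memb$family <- vapply(manifest$genomes[memb$genome_id],
                          function(g) g$taxonomy[["family"]], character(1))
    memb$host_group <- vapply(manifest$genomes[memb$genome_id],
                              function(g) g$taxonomy[["host_group"]],
                              character(1))
  }
  utils::write.table(memb, file.path(config$out_dir, "clusters.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  list(distances = D, tree = tree, partition = partition,
       leaf_order = leaf_order_for_heatmap(tree))
}

#' Classify unclassified genomes against the reference set
#'
#' Reads the unclassified genomes, annotates them with the reference
#' database, rebuilds the joint dendrogram and reports each
#' unclassified genome's cluster, candidate UTU status and
#' no-similarity status.
#'
#' @param config A [run_config()].
#' @param unclassified_paths GenBank files of the query genomes.
#' @return List with the assignment `report`, `partition`, `tree` and
#'   joint signature `table`.
#' @export
run_classify <- function(config, unclassified_paths) {
  log_run(config, "classify")
  ref <- load_manifest(config)
  missing <- unclassified_paths[!file.exists(unclassified_paths)]
  if (length(missing)) {
    stop("missing input file(s): ", paste(missing, collapse = ", "))
  }
  query <- read_genbank(unclassified_paths)
  joint <- dataset_manifest(c(ref$genomes, query$genomes),
                            c(ref$classified,
                              stats::setNames(rep(FALSE,
                                                  length(query$genomes)),
                                              names(query$genomes))))
  db_out <- run_build_db(config, manifest = joint,
                         include_unclassified = TRUE)
  table <- build_signature_table(joint, db_out$db, goms = db_out$goms,
                                 score_floor = config$score_floor)
  tree <- bootstrap_supports(table, n_reps = config$bootstrap_reps,
                             seed = config$seed)
  partition <- collapse(tree, config$collapse_threshold, joint)
  report <- assign_unclassified(partition, joint, table, db_out$db)
  utils::write.table(report, file.path(config$out_dir, "assignments.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utu <- partition$summary[partition$summary$n_classified == 0, ,
                           drop = FALSE]
  utils::write.table(utu, file.path(config$out_dir, "utus.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  list(report = report, partition = partition, tree = tree,
       table = table, manifest = joint)
}

#' Shared-gene mutual information between two virus groups
#'
#' @param config A [run_config()].
#' @param group_a,group_b Disjoint genome-id vectors.
#' @param table Signature table; computed from the config when `NULL`.
#' @return The MI report data frame (also written to `mi.tsv`).
#' @export
run_mi <- function(config, group_a, group_b, table = NULL) {
  log_run(config, "mi")
  if (is.null(table)) {
    db_out <- run_build_db(config)
    table <- run_annotate(config, db_out)
  }
  report <- mean_mi_subsampled(table, group_a, group_b,
                               per_group = config$mi_per_group,
                               reps = config$mi_reps, seed = config$seed)
  utils::write.table(report, file.path(config$out_dir, "mi.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  report
}
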