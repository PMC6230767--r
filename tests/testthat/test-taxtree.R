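# UPGMA, bootstrap supports, collapse, assignment, leaf order, Newick.

dm <- function(vals, ids) {
  n <- length(ids)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  D[upper.tri(D)] <- vals
  D[lower.tri(D)] <- t(D)[lower.tri(D)]
  D
}

test_that("UPGMA reproduces hand-computed merges", {
  D <- dm(c(0.2, 0.6, 0.8), c("A", "B", "C"))  # AB, AC, BC
  tr <- upgma(D)
  expect_equal(sort(tr$height), c(0.2, 0.7))   # (0.6 + 0.8) / 2
  C <- cophenetic_matrix(tr)
  expect_equal(C["A", "B"], 0.2)
  expect_equal(C["A", "C"], 0.7)

  # n = 2: single root at the pair distance
  D2 <- dm(0.35, c("X", "Y"))
  tr2 <- upgma(D2)
  expect_equal(tr2$height, 0.35)

  # equal distances: all internal heights equal
  D3 <- dm(rep(0.5, 6), c("A", "B", "C", "D"))
  expect_equal(upgma(D3)$height, rep(0.5, 3))

  Dna <- D; Dna[1, 2] <- NA
  expect_error(upgma(Dna), "NaN")
})

test_that("UPGMA is order-invariant and matches the naive oracle", {
  set.seed(404)
  ids <- c("L1", "L2", "L3", "L4", "L5")
  D <- dm(runif(10, 0.1, 1), ids)
  ref <- cophenetic_matrix(upgma(D))
  oracle <- oracle_upgma_cophenetic(D)
  expect_equal(ref, oracle, tolerance = 1e-12)
  perms <- combinat_perms(5)
  for (k in seq_len(nrow(perms))) {
    p <- perms[k, ]
    Cp <- cophenetic_matrix(upgma(D[p, p]))
    expect_equal(Cp[ids, ids], ref, tolerance = 1e-12)
  }
})

test_that("UPGMA agrees with hclust average linkage on tie-free matrices", {
  set.seed(405)
  ids <- sprintf("t%02d", 1:8)
  D <- dm(runif(28, 0.05, 1), ids)
  C <- cophenetic_matrix(upgma(D))
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  Ch <- as.matrix(stats::cophenetic(hc))[ids, ids]
  expect_equal(C, Ch, tolerance = 1e-12)
})

test_that("cophenetic matrix reproduces an already-ultrametric input", {
  set.seed(406)
  ids <- sprintf("u%d", 1:6)
  D <- dm(runif(15, 0.1, 1), ids)
  U <- cophenetic_matrix(upgma(D))   # ultrametric by construction
  expect_equal(cophenetic_matrix(upgma(U)), U, tolerance = 1e-12)
})

test_that("bootstrap supports are deterministic, bounded and saturate for identical rows", {
  pb <- rbind(g1 = c(5, 3, 2, 1), g2 = c(5, 3, 2, 1),
              out = c(0, 0, 0, 4))
  colnames(pb) <- sprintf("P%d", 1:4)
  gb <- matrix(numeric(), 3, 0); rownames(gb) <- rownames(pb)
  tab <- cgjtax:::new_signature_table(rownames(pb), pb, gb, pb * 0)
  tr <- bootstrap_supports(tab, n_reps = 50, seed = 9)
  expect_true(all(tr$support >= 0 & tr$support <= 100))
  sets <- cgjtax:::clade_leafsets(tr)
  pair <- which(vapply(sets, function(s)
    setequal(tr$labels[s], c("g1", "g2")), logical(1)))
  expect_equal(tr$support[pair], 100)
  tr2 <- bootstrap_supports(tab, n_reps = 50, seed = 9)
  expect_identical(tr$support, tr2$support)
  expect_error(bootstrap_supports(tab, n_reps = 0), "at least 1")
})

test_that("collapse returns maximal clades strictly below the threshold", {
  run <- family_recovery_run()
  # threshold above the root height -> one cluster
  small <- upgma(dm(c(0.2, 0.4, 0.5), c("A", "B", "C")))
  expect_length(collapse(small, 0.9)$clusters, 1L)
  # merges at exactly the threshold stay split (strict rule); the 5x6
  # tree's root and between-family merges sit at height 1
  expect_length(collapse(run$tree, 1.0)$clusters, 5L)
  # threshold 0 with the strict rule -> every leaf a singleton
  single <- collapse(run$tree, 0)
  expect_length(single$clusters, length(run$tree$labels))
  expect_error(collapse(run$tree, 1.5), "0, 1")
  # co-clustered iff cophenetic distance below threshold
  part <- collapse(run$tree, 0.8)
  C <- cophenetic_matrix(run$tree)
  for (cl in part$clusters) {
    if (length(cl) > 1) expect_true(all(C[cl, cl][upper.tri(C[cl, cl])] < 0.8))
  }
  cl_of <- setNames(rep(names(part$clusters), lengths(part$clusters)),
                    unlist(part$clusters))
  ids <- run$tree$labels
  for (i in ids) {
    same <- ids[C[i, ] < 0.8 & ids != i]
    expect_true(all(cl_of[same] == cl_of[i]))
  }
})

test_that("unclassified genomes are assigned, UTUs and no-similarity flagged", {
  run <- classification_run()
  rep <- run$report
  expect_setequal(rep$genome_id, c(run$novel_ids, "NOGENE01"))
  novel <- rep[rep$genome_id %in% run$novel_ids, ]
  # the two related novel genomes form a candidate UTU cluster
  expect_equal(length(unique(novel$cluster_id)), 1L)
  expect_true(all(novel$is_utu))
  expect_true(all(novel$n_classified == 0))
  # the gene-free genome shows no similarity to the classified set
  bare <- rep[rep$genome_id == "NOGENE01", ]
  expect_true(bare$no_similarity)
  # an unclassified genome clustered with classified members reports
  # that family composition
  joint2 <- run$joint
  cls <- joint2$classified
  cls[["FAM01_V01"]] <- FALSE
  man2 <- dataset_manifest(joint2$genomes, cls)
  part2 <- collapse(upgma(distance_matrix(run$table)), 0.8, man2)
  rep2 <- assign_unclassified(part2, man2, run$table, run$db)
  row <- rep2[rep2$genome_id == "FAM01_V01", ]
  expect_equal(row$cluster_families, "FAM01")
  expect_false(row$is_utu)
  expect_equal(row$n_classified, 3)
})

test_that("heat-map leaf order is a stable permutation of the leaves", {
  run <- family_recovery_run()
  ord <- leaf_order_for_heatmap(run$tree)
  expect_setequal(ord, run$tree$labels)
  expect_identical(ord, leaf_order_for_heatmap(run$tree))
  # family members are contiguous in the order (families are clades)
  fam <- sub("_V.*$", "", ord)
  expect_equal(sum(fam[-1] != fam[-length(fam)]) + 1L,
               length(unique(fam)))
})

test_that("Newick export carries supports and height-difference branch lengths", {
  skip_if_not_installed("ape")
  run <- family_recovery_run()
  nwk <- write_newick(run$tree)
  tr <- ape::read.tree(text = nwk)
  expect_setequal(tr$tip.label, run$tree$labels)
  # leaf depths from the root equal the root height (ultrametric)
  depths <- ape::node.depth.edgelength(tr)[seq_along(tr$tip.label)]
  expect_equal(unname(depths), rep(max(run$tree$height),
                                   length(tr$tip.label)),
               tolerance = 1e-8)
  expect_true(all(as.numeric(tr$node.label) >= 0 &
                    as.numeric(tr$node.label) <= 100))
})
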