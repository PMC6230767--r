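# Pairwise similarity, clustering, alignment, profile HMMs, scanning.

test_that("local alignment reproduces the classic worked example", {
  sc <- scoring_system(matrix = "BLOSUM50", gap_open = 8, gap_extend = 8)
  expect_equal(sw_score("HEAGAWGHEE", "PAWHEAE", sc), 28)
  expect_equal(oracle_sw("HEAGAWGHEE", "PAWHEAE", sc$matrix, 8, 8), 28)
})

test_that("local alignment scores match the quadratic DP oracle", {
  sc <- scoring_system()
  set.seed(101)
  for (rep in 1:20) {
    a <- random_aa(sample(5:25, 1))
    b <- random_aa(sample(5:25, 1))
    expect_equal(sw_score(a, b, sc),
                 oracle_sw(a, b, sc$matrix, sc$gap_open, sc$gap_extend),
                 info = paste(a, b))
  }
  expect_error(sw_score("", "ACDE", sc), "empty")
})

test_that("similarity edges are symmetric, floored and self-maximal", {
  set.seed(7)
  base <- random_aa(50)
  prot <- toy_protein_df(c(a = base, b = base, c = random_aa(50),
                           d = random_aa(12)))
  sc <- scoring_system()
  edges <- pairwise_similarity(prot, sc, min_score = 0)
  key <- function(e) paste(pmin(e$protein_a, e$protein_b),
                           pmax(e$protein_a, e$protein_b))
  expect_false(anyDuplicated(key(edges)) > 0)  # each pair scored once
  # reversing the input order reproduces the same scores
  edges_rev <- pairwise_similarity(prot[rev(seq_len(nrow(prot))), ], sc,
                                   min_score = 0)
  m1 <- edges$bit_score[order(key(edges))]
  m2 <- edges_rev$bit_score[order(key(edges_rev))]
  expect_equal(m1, m2)
  # identical sequences give the maximal score involving either
  ab <- edges$bit_score[key(edges) == "a b"]
  expect_true(all(ab >= edges$bit_score[edges$protein_a == "a" |
                                          edges$protein_b == "a"]))
  # unrelated short random proteins do not pass the default threshold
  def <- pairwise_similarity(prot, sc)
  expect_false(any(key(def) %in% c("a d", "b d", "c d")))
})

test_that("threshold components clustering follows the graph definition", {
  prot <- toy_protein_df(c(A = "AAAA", B = "CCCC", C = "DDDD"))
  edges <- data.frame(protein_a = c("A", "B"), protein_b = c("B", "C"),
                      bit_score = c(40, 5), stringsAsFactors = FALSE)
  cl <- cluster_proteins(edges, prot, threshold = 20)
  sets <- lapply(cl, function(x) x$members$feature_id)
  expect_equal(sets, list(c("A", "B"), "C"))
  expect_equal(vapply(cl, `[[`, character(1), "cluster_id"),
               c("PC0001", "PC0002"))

  none <- cluster_proteins(edges[0, ], prot, threshold = 20)
  expect_length(none, 3L)
  expect_true(all(lengths(lapply(none, function(x) x$members$feature_id)) == 1))

  full <- data.frame(protein_a = c("A", "A", "B"),
                     protein_b = c("B", "C", "C"),
                     bit_score = c(50, 50, 50), stringsAsFactors = FALSE)
  one <- cluster_proteins(full, prot, threshold = 20)
  expect_length(one, 1L)
  expect_equal(one[[1]]$n_member_viruses, 3L)

  # invariance under edge permutation
  perm <- cluster_proteins(full[c(3, 1, 2), ], prot, threshold = 20)
  expect_identical(one, perm)
})

test_that("center-star alignment preserves sequences and handles gaps", {
  prot <- toy_protein_df(c(x = "ACDE", y = "ACE"))
  cl <- list(cluster_id = "PC0001",
             members = data.frame(genome_id = c("x", "y"),
                                  feature_id = c("x", "y"),
                                  stringsAsFactors = FALSE),
             n_member_viruses = 2L)
  msa <- align_cluster(cl, prot)
  expect_equal(unname(msa), c("ACDE", "AC-E"))

  single <- list(cluster_id = "PC0002",
                 members = data.frame(genome_id = "x", feature_id = "x"),
                 n_member_viruses = 1L)
  expect_equal(unname(align_cluster(single, prot)), "ACDE")

  same <- toy_protein_df(c(p = "MKLV", q = "MKLV"))
  cl2 <- list(cluster_id = "PC0003",
              members = data.frame(genome_id = c("p", "q"),
                                   feature_id = c("p", "q")),
              n_member_viruses = 2L)
  expect_equal(unname(align_cluster(cl2, same)), c("MKLV", "MKLV"))

  # ungapping any row returns the original sequence
  set.seed(33)
  base <- random_aa(40)
  variants <- vapply(1:4, function(i) {
    ch <- strsplit(base, "")[[1]]
    drop <- sample(40, sample(0:3, 1))
    if (length(drop)) ch <- ch[-drop]
    paste(ch, collapse = "")
  }, character(1))
  names(variants) <- sprintf("v%d", 1:4)
  prot3 <- toy_protein_df(variants)
  cl3 <- list(cluster_id = "PC0004",
              members = data.frame(genome_id = names(variants),
                                   feature_id = names(variants)),
              n_member_viruses = 4L)
  msa3 <- align_cluster(cl3, prot3)
  expect_length(unique(nchar(msa3)), 1L)
  expect_equal(gsub("-", "", msa3), variants)
})

test_that("profile HMM construction follows the stated count rules", {
  p <- build_pphmm("AAA")
  expect_equal(p$n_match_states, 3L)
  expect_true(all(p$match_emissions[, "A"] ==
                    apply(p$match_emissions, 1, max)))
  expect_equal(rowSums(p$match_emissions), rep(1, 3), tolerance = 1e-9)
  expect_true(all(p$match_emissions > 0))
  expect_equal(rowSums(p$transitions[, 1:3]), rep(1, 4), tolerance = 1e-9)

  # columns at exactly 50% gaps are still match states
  p2 <- build_pphmm(c("A-", "AA", "-A", "--"))
  expect_equal(p2$n_match_states, 2L)
  p3 <- build_pphmm(c("AX", "-X", "-X", "-X"))
  expect_equal(p3$n_match_states, 1L)  # col1 75% gaps dropped

  # pseudocount arithmetic: column {A, A}, alpha = 1
  p4 <- build_pphmm(c("A", "A"), alpha = 1)
  bgA <- cgjtax:::AA_BACKGROUND[["A"]]
  expect_equal(unname(p4$match_emissions[1, "A"]), (2 + bgA) / 3,
               tolerance = 1e-12)

  expect_error(build_pphmm(c("AA", "A")), "unequal")
})

test_that("forward scores equal exhaustive path enumeration on toy models", {
  set.seed(55)
  msas <- list(c("ACD", "ACD", "AC-"),
               c("MKL", "MRL"),
               c("WYV-QQ", "WY-AQQ", "WYVAQ-"),
               "HHH")
  for (msa in msas) {
    p <- build_pphmm(msa)
    for (len in c(1, 2, 4, 6)) {
      s <- random_aa(len)
      expect_equal(forward_bits(p, s), oracle_forward_bits(p, s),
                   tolerance = 1e-6, info = paste(msa[1], s))
    }
    # also score a member sequence itself
    s <- gsub("-", "", msa[1])
    expect_equal(forward_bits(p, s), oracle_forward_bits(p, s),
                 tolerance = 1e-6)
  }
})

test_that("a cluster member outscores random decoys against its PPHMM", {
  set.seed(77)
  seqs <- random_aa(40)
  p <- build_pphmm(seqs)
  self <- forward_bits(p, seqs)
  expect_gt(self, 0)
  decoys <- vapply(1:20, function(i) forward_bits(p, random_aa(40)),
                   numeric(1))
  expect_true(all(self >= decoys))
})

test_that("scanning keeps the best hit per PPHMM above the floor", {
  set.seed(88)
  gene <- random_aa(60)
  mutant <- local({
    ch <- strsplit(gene, "")[[1]]
    idx <- sample(60, 20)
    for (i in idx) ch[i] <- sample(setdiff(cgjtax:::AA20, ch[i]), 1)
    paste(ch, collapse = "")
  })
  g <- toy_genome("SCAN1", translations = c(gene, mutant),
                  strands = c("+", "-"))
  db <- structure(list(pphmms = list(PC0001 = local({
    p <- build_pphmm(gene)
    p$pphmm_id <- "PC0001"
    p
  })), provenance = list()), class = "cgj_pphmm_db")
  hits <- scan_genome(g, db)
  expect_equal(nrow(hits), 1L)   # best-hit rule: one row per PPHMM
  expect_equal(hits$feature_id, "SCAN1.cds1")  # exact copy wins
  expect_gt(hits$score, 0)
  expect_equal(hits$strand, "+")

  nogene <- annotated_genome("EMPTY", segment_lengths = 100L,
                             features = g$features[0, ])
  expect_equal(nrow(scan_genome(nogene, db)), 0L)
})

test_that("singleton filtering applies the family-size rule and is idempotent", {
  # families: Big (5 viruses), Small (2 viruses)
  genomes <- c(lapply(1:5, function(i)
    toy_genome(sprintf("BIG%d", i), family = "Bigviridae")),
    lapply(1:2, function(i)
      toy_genome(sprintf("SML%d", i), family = "Smallviridae")))
  man <- dataset_manifest(genomes, classified = TRUE)
  mk <- function(id, members) {
    p <- build_pphmm("MKLVWY")
    p$pphmm_id <- id
    p$member_virus_ids <- members
    p
  }
  db <- structure(list(pphmms = list(
    P1 = mk("P1", "BIG1"),             # singleton in big family -> drop
    P2 = mk("P2", "SML1"),             # singleton in 2-virus family -> keep
    P3 = mk("P3", c("BIG1", "BIG2"))), # two viruses -> keep
    provenance = list()), class = "cgj_pphmm_db")
  out <- filter_singletons(db, man)
  expect_setequal(names(out$pphmms), c("P2", "P3"))
  expect_identical(filter_singletons(out, man), out)
})

test_that("external similarity scores import deduplicated", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "scores.tsv")
  writeLines(c("a\tb\t40", "b\ta\t35", "a\tc\t10"), path)
  sc <- import_similarity_scores(path)
  expect_equal(nrow(sc), 2L)
  expect_equal(sc$bit_score[sc$protein_a == "a" & sc$protein_b == "b" |
                              sc$protein_a == "b" & sc$protein_b == "a"], 40)
})
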