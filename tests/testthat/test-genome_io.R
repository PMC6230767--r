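# GenBank/metadata reading and tabular round trips.

gbk_fixture <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  # 120 nt genome; CDS2 on the minus strand, CDS3 without /translation
  seq <- paste0(
    "atgcatgaagcaggtgcatggggtcatgaagaataa",      # 1..36  MHEAGAWGHE
    strrep("acgt", 6),                            # 37..60 spacer
    "ttacttcggcatcgccgcaaacat",                   # 61..84 revcomp of MFAAMPK..
    "acgtacgtacgt",                               # 85..96 spacer
    "atgaaaccggaagaataa",                         # 97..114 MKPEE
    "acgtac")                                     # tail
  feats <- c(
    "     CDS             1..36",
    "                     /translation=\"MHEAGAWGHE\"",
    "     CDS             complement(61..84)",
    "                     /translation=\"MFAADPK\"",
    "     CDS             97..114")
  lines <- c(
    sprintf("LOCUS       TESTA1 %d bp    DNA     linear   PHG 01-JAN-2026",
            nchar(seq)),
    "DEFINITION  Test record one.",
    "ACCESSION   TESTA1",
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", nchar(seq)),
    feats,
    "ORIGIN")
  chunks <- substring(seq, seq(1, nchar(seq), 60),
                      pmin(seq(1, nchar(seq), 60) + 59, nchar(seq)))
  for (i in seq_along(chunks)) {
    grp <- substring(chunks[i], seq(1, nchar(chunks[i]), 10),
                     pmin(seq(1, nchar(chunks[i]), 10) + 9,
                          nchar(chunks[i])))
    lines <- c(lines, sprintf("%9d %s", (i - 1L) * 60L + 1L,
                              paste(grp, collapse = " ")))
  }
  lines <- c(lines, "//")
  path <- file.path(dir, "testa.gbk")
  writeLines(lines, path)
  path
}

test_that("GenBank records parse with coordinates, strands and translations", {
  path <- gbk_fixture()
  man <- read_genbank(path)
  expect_length(man$genomes, 1L)
  g <- man$genomes[["TESTA1"]]
  expect_equal(nrow(g$features), 3L)
  # complement(61..84) keeps GenBank coordinates with strand "-"
  expect_equal(g$features$start[2], 61L)
  expect_equal(g$features$end[2], 84L)
  expect_equal(g$features$strand[2], "-")
  expect_equal(g$features$strand[1], "+")
  # CDS without /translation is translated with table 11 (stop stripped)
  expect_equal(g$features$translation[3], "MKPEE")
  expect_false(man$classified[["TESTA1"]])
})

test_that("multi-record files yield one genome per LOCUS", {
  dir <- withr::local_tempdir()
  p1 <- gbk_fixture(dir)
  two <- c(readLines(p1), gsub("TESTA1", "TESTB1", readLines(p1)))
  p2 <- file.path(dir, "two.gbk")
  writeLines(two, p2)
  man <- read_genbank(p2)
  expect_setequal(names(man$genomes), c("TESTA1", "TESTB1"))
})

test_that("simulated GenBank files round-trip through the parser", {
  sim <- cached("io_roundtrip", simulate_genomes(
    sim_config(n_families = 2, members_per_family = 2,
               genes_per_family = 3, seed = 5),
    dir = withr::local_tempdir(.local_envir = teardown_env())))
  for (gid in names(sim$manifest$genomes)) {
    g <- sim$manifest$genomes[[gid]]
    expect_gte(nrow(g$features), 1L)
    # re-derive each protein from the nucleotide record
    for (k in seq_len(nrow(g$features))) {
      nt <- substr(g$segment_seqs, g$features$start[k], g$features$end[k])
      dna <- Biostrings::DNAString(nt)
      if (g$features$strand[k] == "-") {
        dna <- Biostrings::reverseComplement(dna)
      }
      aa <- sub("\\*$", "", as.character(
        Biostrings::translate(dna,
                              genetic.code = Biostrings::getGeneticCode("11"))))
      expect_identical(aa, g$features$translation[k])
    }
  }
})

test_that("protein extraction is strand-aware under genome reversal", {
  sim <- cached("io_roundtrip", simulate_genomes(
    sim_config(n_families = 2, members_per_family = 2,
               genes_per_family = 3, seed = 5),
    dir = withr::local_tempdir(.local_envir = teardown_env())))
  g <- sim$manifest$genomes[[1]]
  L <- g$segment_lengths
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(g$segment_seqs)))
  f <- g$features
  flipped <- data.frame(
    feature_id = f$feature_id, segment_index = 0L,
    start = L - f$end + 1L, end = L - f$start + 1L,
    strand = ifelse(f$strand == "+", "-", "+"),
    translation = f$translation, stringsAsFactors = FALSE)
  for (k in seq_len(nrow(flipped))) {
    dna <- Biostrings::DNAString(substr(rc, flipped$start[k],
                                        flipped$end[k]))
    if (flipped$strand[k] == "-") dna <- Biostrings::reverseComplement(dna)
    aa <- sub("\\*$", "", as.character(
      Biostrings::translate(dna,
                            genetic.code = Biostrings::getGeneticCode("11"))))
    expect_identical(aa, f$translation[k])
  }
})

test_that("metadata attaches taxonomy by accession and flags the rest", {
  dir <- withr::local_tempdir()
  p1 <- gbk_fixture(dir)
  two <- c(readLines(p1), gsub("TESTA1", "TESTB1", readLines(p1)))
  writeLines(two, file.path(dir, "two.gbk"))
  md <- data.frame(baltimore_group = "I", order = "Caudovirales",
                   family = "Myoviridae", subfamily = "", genus = "Tvirus",
                   virus_name = "Test virus A", genbank_accession = "TESTA1",
                   refseq_accession = "", description = "test",
                   host_group = "bacteria", stringsAsFactors = FALSE)
  mdp <- file.path(dir, "md.tsv")
  utils::write.table(md, mdp, sep = "\t", quote = FALSE, row.names = FALSE)
  man <- read_metadata(mdp, read_genbank(file.path(dir, "two.gbk")))
  expect_equal(man$genomes[["TESTA1"]]$taxonomy[["family"]], "Myoviridae")
  expect_true(man$classified[["TESTA1"]])
  expect_false(man$classified[["TESTB1"]])

  md2 <- rbind(md, md)
  utils::write.table(md2, mdp, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_metadata(mdp, read_genbank(file.path(dir, "two.gbk"))),
               "duplicate accession")
})

test_that("metadata can join segments into one multi-segment genome", {
  dir <- withr::local_tempdir()
  p1 <- gbk_fixture(dir)
  two <- c(readLines(p1), gsub("TESTA1", "TESTB1", readLines(p1)))
  writeLines(two, file.path(dir, "two.gbk"))
  md <- data.frame(baltimore_group = "I", order = "", family = "Fam",
                   subfamily = "", genus = "", virus_name = "seg virus",
                   genbank_accession = "TESTA1;TESTB1",
                   refseq_accession = "", description = "",
                   host_group = "bacteria", stringsAsFactors = FALSE)
  mdp <- file.path(dir, "md.tsv")
  utils::write.table(md, mdp, sep = "\t", quote = FALSE, row.names = FALSE)
  man <- read_metadata(mdp, read_genbank(file.path(dir, "two.gbk")))
  expect_length(man$genomes, 1L)
  g <- man$genomes[[1]]
  expect_length(g$segment_lengths, 2L)
  expect_equal(nrow(g$features), 6L)
  expect_equal(sort(unique(g$features$segment_index)), c(0L, 1L))
})

test_that("write_table round-trips numeric matrices at 1e-9", {
  dir <- withr::local_tempdir()
  set.seed(42)
  m <- matrix(runif(30), 5, 6,
              dimnames = list(sprintf("g%d", 1:5), sprintf("c%d", 1:6)))
  path <- file.path(dir, "m.tsv")
  write_table(m, path, kind = "distances")
  back <- read_matrix_tsv(path)
  expect_equal(back, m, tolerance = 1e-9)

  empty <- matrix(numeric(), 0, 3,
                  dimnames = list(NULL, c("a", "b", "c")))
  write_table(empty, file.path(dir, "e.tsv"), kind = "signatures")
  expect_equal(colnames(read_matrix_tsv(file.path(dir, "e.tsv"))),
               c("a", "b", "c"))

  m[1, 1] <- NaN
  expect_error(write_table(m, path, kind = "distances"), "non-finite")
})

test_that("FASTA plus GFF3 input yields the same genomes as GenBank", {
  skip_if_not_installed("rtracklayer")
  sim <- cached("io_roundtrip", simulate_genomes(
    sim_config(n_families = 2, members_per_family = 2,
               genes_per_family = 3, seed = 5),
    dir = withr::local_tempdir(.local_envir = teardown_env())))
  g <- sim$manifest$genomes[[1]]
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "g.fasta")
  writeLines(c(paste0(">", g$genome_id), g$segment_seqs), fa)
  gff <- file.path(dir, "g.gff3")
  f <- g$features
  writeLines(c("##gff-version 3",
               sprintf("%s\tsim\tCDS\t%d\t%d\t.\t%s\t0\tID=cds%d",
                       g$genome_id, f$start, f$end, f$strand,
                       seq_len(nrow(f)))), gff)
  man <- read_fasta_gff(fa, gff)
  g2 <- man$genomes[[g$genome_id]]
  expect_equal(nrow(g2$features), nrow(f))
  expect_equal(g2$features$translation, f$translation)
  expect_equal(g2$features$start, f$start)
  expect_equal(g2$features$strand, f$strand)
})
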