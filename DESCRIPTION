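Package: cgjtax
Title: Genome-Based Virus Classification with Composite Generalized
    Jaccard Distances
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Annotates virus genomes against a database of protein
    profile hidden Markov models (PPHMMs) built from clustered protein
    families, summarises each genome as a PPHMM similarity signature
    plus a genome-organisation (GOM) signature based on distance
    correlations of signed gene-location profiles, and computes
    composite generalized Jaccard (CGJ) distances between genomes.
    Builds bootstrapped UPGMA dendrograms from the distances, delimits
    family-equivalent clusters at a distance threshold, assigns
    unclassified genomes to clusters or to candidate unassigned
    taxonomic units, and scores genes shared between two virus groups
    by subsampled mutual information.  Includes a synthetic-genome
    generator with known family and genus structure so the whole
    pipeline can be exercised without external sequence downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    Rcpp,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ape,
    phangorn,
    rtracklayer,
    GenomicRanges,
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
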