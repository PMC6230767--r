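---
title: "Methods: genome signatures, CGJ distances and family delimitation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genome signatures, CGJ distances and family delimitation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its model and the design
choices behind it: what each stage computes, which parameters matter,
what the synthetic benchmark does and does not establish, and where the
numerical edges are.

## The model

`cgjtax` measures relatedness between annotated virus genomes on two
complementary axes — which genes a genome carries, and how those genes
are arranged — and combines them into a single bounded distance.

### Gene content: the PPHMM signature

Protein sequences are extracted from the reference genomes (CDS
features only; segments of a segmented genome are pooled into one
protein set). All-vs-all local alignment scores are computed and
converted to bits with the Karlin–Altschul transform
$(\lambda S - \ln K)/\ln 2$ at the fixed gapped-BLOSUM62 constants
$\lambda = 0.267$, $K = 0.041$. Fixed constants, rather than per-pair
estimation, keep every score on one scale; absolute calibration is
unimportant because downstream statistics are ratios of scores, not
significance tests. Proteins are clustered by connected components of
the similarity graph at a bit-score threshold (default 30 bits —
comfortably above the 13–16 bit scores that unrelated random proteins
of typical gene length reach under these constants, and far below the
scores of genuinely homologous genes). An MCL-style
expansion/inflation clustering (inflation 2.0) is available for graphs
where components chain distinct families together.

Each cluster is aligned by center-star progressive alignment (the
center is the member with the greatest summed pairwise bit score) and
turned into a profile hidden Markov model:

* match states are alignment columns with gap fraction ≤ 0.5;
* match emissions are column residue counts plus background-weighted
  pseudocounts of total strength α = 1, normalised;
* insert states emit the Robinson–Robinson amino-acid background;
* transitions are estimated from per-row match/insert/delete state
  paths with pseudocount 1 per transition type.

Scanning scores every protein of a genome against every PPHMM with the
forward algorithm in log space — summing over all alignments rather
than taking the single best path — and reports the log-odds against
the background null in bits. Per (genome, PPHMM) the best-scoring
protein is the hit; hits must strictly exceed the score floor
(default 0 bits, so "similarity detected" means positive log-odds).
The PPHMM signature is the vector of hit scores, zero where no hit.

### Gene arrangement: the GOM signature

Each hit contributes a signed location $s \cdot m$: $m \in (0, 1]$ is
the fractional midpoint of the gene over the concatenated genome
length and $s = \pm 1$ its strand. This encoding makes both gene order
(via the magnitude) and orientation (via the sign) visible to a single
dependence statistic. The location profiles of a family's classified
members, stacked row-wise, form the family's genome-organisation model
(GOM); one-member families are allowed. A genome's GOM signature is
the vector of classic (biased) sample distance correlations between
its location profile and each family GOM, treating the PPHMM columns
as observations — scalar on the profile side, one column vector per
member on the GOM side. Degenerate cases (constant profile, e.g. a
genome with no hits) return 0 — no organisational evidence — rather
than NaN. The biased estimator is used because signature tables have
many more PPHMM columns than GOM members, where the bias correction
buys nothing and the classic form keeps the statistic in [0, 1]
exactly.

### The composite distance

For genomes $i, j$ with PPHMM signatures $p_i, p_j$ and GOM signatures
$g_i, g_j$:

$$\mathrm{CGJ}(i,j) = \sqrt{J(p_i, p_j)\, J(g_i, g_j)},\qquad
  J(a, b) = \frac{\sum_k \min(a_k, b_k)}{\sum_k \max(a_k, b_k)}$$

and the CGJ distance is $1 - \mathrm{CGJ}$. Two all-zero vectors get
$J = 0$, hence distance 1: genomes with no detectable genes share no
evidence of relatedness, and returning 1 would spuriously cluster
annotation failures. The geometric mean is unweighted; a configuration
exponent exists but defaults to the plain square root. If a pruned
table carries no GOM columns the PPHMM Jaccard stands alone.

### Dendrogram, bootstrap, delimitation

UPGMA (size-weighted average linkage) turns the distance matrix into a
rooted ultrametric dendrogram whose node heights are merge distances
on the full CGJ scale — deliberately not half-distances, so that the
0.8 family cut-off and tree heights live on the same axis. Ties are
broken by the lexicographically smallest pair of cluster anchor ids,
which makes the tree a deterministic function of the distance matrix,
invariant to input order.

Clade uncertainty comes from bootstrapping the signature table: each
of the (by default 100; 50–100 is the sensible range) pseudoreplicates
resamples the PPHMM columns with replacement and keeps the GOM columns
fixed, since GOM scores derive from the same gene set being resampled;
a switch enables joint resampling of both blocks for users who prefer
to treat the blocks symmetrically. A clade's support is the percentage
of replicate trees containing exactly its leaf set (rooted-clade
comparison — UPGMA trees are rooted, so bipartitions would discard the
root).

Collapsing the tree at a threshold (default 0.8) yields the maximal
clades whose root height is strictly below the threshold; leaves only
attached above it become singletons. The strict inequality makes the
boundary behaviour explicit: at threshold 0 every leaf is a singleton.
Thresholds are accepted on the closed interval [0, 1]. Unclassified
genomes are reported with the family composition of their cluster;
clusters containing no classified genome are candidate unassigned
taxonomic units (UTUs); genomes scoring zero on every PPHMM that has a
classified member are reported as showing no similarity to the
classified dataset. For classification runs the database is built over
classified and unclassified genomes jointly — otherwise two related
novel genomes could never cluster with each other — while GOMs always
come from classified members only.

Single-virus PPHMMs are filtered before annotation when their one
member belongs to a family with more than two viruses: in a
well-sampled family, a gene seen in a single member carries no grouping
signal, whereas for unclassified viruses or two-member families it may
be the only evidence available.

### Shared-gene mutual information

To ask which gene features separate two virus groups, each PPHMM still
present in either group is scored by the plug-in mutual information
(in bits) between group membership and feature presence
(score > 0), averaged over repeated subsamples of two genomes per
group (100 replicates by default). With two genomes per group the
per-replicate estimator is deliberately coarse — the subsampling is
what prevents large, well-sampled groups from swamping the statistic —
so the report carries the per-PPHMM standard deviation alongside the
mean, and the binary/binary estimator bounds every value by 1 bit. A
quantile-binned variant (`bins > 2`) is available for users who want
score magnitude, not just presence, to count.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| clustering threshold | 30 | bits | edge cut for protein families |
| emission pseudocount α | 1 | counts | Laplace strength toward background |
| match-column gap limit | 0.5 | fraction | columns above it become inserts |
| score floor | 0 | bits | minimum log-odds for a hit |
| collapse threshold | 0.8 | CGJ distance | family-equivalent delimitation |
| bootstrap replicates | 100 | count | clade support resolution |
| MI replicates × per-group | 100 × 2 | count | subsampled MI estimator |

The 0.8 collapse threshold is the empirical divergence separating
within-family from between-family comparisons of eukaryotic viruses
and is the one value a user should treat as biologically meaningful
rather than tunable. The remaining defaults are standard
profile-HMM/graph-clustering practice.

## The synthetic benchmark

The generator founds each family with an ancestor — ordered random
protein genes (length 60–120 aa), strands drawn 3:1 forward:reverse,
random intergenic spacers — and derives members by uniform residue
substitution at a configured rate (default 0.15), whole-gene loss
(default 0.1, always retaining at least one gene), and strand
inversion (default 0.05). A shared-gene fraction plants genes from a
common pool into several families (mosaicism). Proteins are
back-translated with the most frequent host codon per residue and
emitted as GenBank flat files plus a metadata table, so every run
exercises the same readers as real data. Genomes, not residues, are
the unit of realism: substitutions are uniform over the 19 alternative
residues with no rate matrix or indel process, which is sufficient to
create graded homology signal for an aligner but says nothing about
real evolutionary dynamics.

The two-regime benchmark contrasts a "eukaryote-like" block (four
cohesive families, two genus labels each) with a "phage-like" block in
which four family labels each group two independently founded genera:
within-genus distances are small in both blocks, while phage
between-genus distances approach 1 because the genera share no genes.

Passing tests on these data show that the pipeline recovers known
structure under its own generative assumptions — conserved gene
content and synteny within families, none across them. They do not
show performance on real genomes, where homology detection (not
clustering) is the limiting step: real protein families diverge far
beyond 15 % and alignment sensitivity, not the distance framework,
decides what is detectable.

Problem sizes used by the test-suite and the acceptance script — 30
genomes for family recovery, 48 for the two-regime contrast, 100
bootstrap and MI replicates — were chosen as the smallest sets on
which the qualitative contrasts are stable across seeds.

## Numerical choices and degenerate inputs

* All-zero signature pairs: $J = 0$, distance 1 (see above).
* Distance correlation with zero distance variance on either side
  returns 0.
* Forward scores are computed in log space with log-sum-exp guards;
  residues outside the 20 standard amino acids are skipped.
* UPGMA and clustering tie-breaks are lexicographic on ids, so every
  stage is a pure function of (inputs, configuration, seed); bootstrap
  and MI draws are the only RNG consumers and restore the caller's RNG
  state.
* CDS with internal stop codons are kept with stops stripped (warning);
  a trailing stop is silently removed.
* Circular genomes are treated as linearized at the annotated origin.
* Multi-segment genomes: coordinates stay per-segment; location
  profiles use the concatenated coordinate system in the segment order
  given by the metadata's accession list.

## Known limitations

* The aligner-based similarity search is quadratic in the number of
  proteins; for thousands of genomes, import of externally computed
  scores (`import_similarity_scores()`) is the intended path.
* No E-value calibration and no domain-level multi-hit parsing: one
  best hit per (genome, PPHMM).
* No six-frame ORF discovery — annotated CDS only.
* The location encoding collapses each gene to a signed midpoint;
  rearrangements that preserve midpoints and strands are invisible to
  the GOM statistic.
* Bootstrap supports resample gene features, not genomes; they measure
  robustness of clades to the sampled gene set, not sampling error
  over taxa.
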