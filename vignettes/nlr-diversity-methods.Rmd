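---
title: "Methods: quantifying NLR allelic diversity and its genomic correlates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying NLR allelic diversity and its genomic correlates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nlrdiversity)
```

# Overview

`nlrdiversity` links two views of a plant immune-receptor family. The first
is *allelic diversity across a species*: per-position Shannon entropy of
clade alignments assembled from many accessions, summarized into a binary
highly-variable (hv) versus non-hv classification per gene. The second is
the *genomic context of each gene in one reference accession*: expression,
gene-body CG methylation, transposable-element (TE) proximity, physical
clustering, and population-genetic signatures of selection (pi, Tajima's D,
piN/piS, empirical-tail tests). The package provides the estimators, the
gene-set comparison machinery, and a generator that simulates every input
with known ground truth.

# Entropy classification

For a clade alignment and a designated focal sequence (the reference
accession's allele), only columns where the focal sequence is non-gap are
scored, and profile position *k* is the *k*-th non-gap focal residue — the
profile therefore lives in the focal protein's own coordinates and profiles
from different clades are directly comparable. Column entropy is the plug-in
estimator in bits, `H = -sum(p * log2(p))`; a gene is hv when at least
`min_positions = 10` positions exceed `threshold = 1.5` bits, strictly.

Choices worth making explicit:

* **Gaps are excluded from column counts**, not treated as a 21st symbol,
  and ambiguous residues (`X`) are likewise dropped with the effective
  sample size recorded per column. Treating indel presence as an allele
  would conflate alignment uncertainty with substitution diversity; a flag
  recording `n_effective` lets users audit columns with poor support.
* **Columns with fewer than 2 informative residues score 0** and are
  flagged `low_support` rather than propagating an undefined value into the
  per-gene mean; an all-gap column (impossible in focal coordinates) is an
  error, never a silent zero.
* The estimator is deliberately **uncorrected** (no shrinkage or
  bias-corrected entropy): the 1.5-bit threshold is calibrated against
  plug-in estimates, and 1.5 bits already requires at least three amino
  acids at appreciable frequency, so small-sample inflation cannot by
  itself push a conserved column over the rule.

# Diversity statistics

`diversity_stats()` accepts nucleotide alignments or 0/1 haplotype
matrices. pi is the average number of pairwise differences over all C(n,2)
pairs; S counts columns with at least two observed non-missing alleles;
Watterson's theta is S/a1; Tajima's D uses the 1989 variance constants and
is **NA when S = 0** (the statistic has 0/0 form; coercing it to zero would
bias downstream medians toward neutrality). At n = 3 the variance constants
vanish identically, so D is 0 when the numerator is 0 and NA otherwise.

Two normalization conventions are fixed and documented rather than
inferred:

* **Per-site values divide by the full alignment/CDS length L**, including
  monomorphic and gap-containing columns. Gaps and N reduce the pairwise
  comparisons, not L. The alternative (accessible-site normalization)
  changes per-site values on gappy alignments; using a fixed gene length
  keeps genes comparable against genome-wide backgrounds computed from VCF
  slices, where monomorphic positions never appear as records
  (`stats_from_vcf_gene()` therefore takes the CDS length explicitly).
* **A column with one real allele plus gaps is not segregating** — indels
  are not SNPs here.

VCF input keeps biallelic SNPs only; sites with any missing genotype among
the retained accessions are dropped and counted, and diploid genotypes
expand to two haplotypes with heterozygous-site counts reported (the study
species is selfing, so heterozygous calls are rare but auditable rather
than silently resolved).

## piN/piS

`pin_pis()` implements unweighted Nei–Gojobori (NG86) counting: per codon
position, the potential synonymous fraction is the share of the non-stop
single-nucleotide changes that preserve the amino acid (so synonymous plus
nonsynonymous potential sites sum to exactly 3 per codon — the stop
exclusion is the only adjustment); pairwise differences are averaged over
the shortest mutational pathways between codons, excluding pathways through
stop codons (with an equal-weight fallback over all pathways in the rare
case every one is blocked). piN is the ratio of pairwise-mean differences to
pairwise-mean sites, with no multiple-hit correction; the ratio is NA when
piS = 0. NG86 was chosen because it is fully specifiable and deterministic;
likelihood-based codon models are out of scope.

One property of NG86 deserves a note: pathway averaging can assign a small
nonsynonymous difference to codon pairs whose true history is purely
synonymous (two synonymous steps where one path order crosses a
nonsynonymous intermediate, e.g. AGA–CGC via AGC). Under the simulator's
omega = 0 setting the protein alignments are exactly monomorphic, yet
measured piN occasionally sits just above zero (at most ~0.01 in 200
simulated clades). Tests assert the contract at that level rather than
exact zero.

## Domains and windows

Domain-restricted statistics label each alignment column with the plurality
domain class (CC, TIR, NBARC, LRR) among non-gap sequences, from
per-sequence annotations given in each sequence's own ungapped coordinates;
ties go to "none". Sliding tracks use 300 bp windows advancing 75 bp in
focal CDS coordinates (incomplete tail windows dropped; midpoint reported
at start + 149), so tracks from different clades share an x-axis; whether
the window slice includes alignment columns where the focal sequence is
gapped was an open choice — they are excluded, keeping every window exactly
300 focal bases.

## Empirical tails

Tail flags compare a gene's statistic against a genome-wide background
using linearly interpolated quantiles (R type 7) and strict inequality, so
a value exactly at the 95th percentile is not in the tail. The joint
balancing-selection flag requires the top 5% of both the pi and the D
background distributions.

# Genomic features

* **TPM**: counts/length rates scaled to 1e6 per sample; replicate TPMs are
  averaged **before** the log2(x + 1) transform (order matters at low
  counts and follows the convention that summaries are on the TPM scale).
* **Methylation**: cytosines need >= 5 reads; per-cytosine percentages are
  averaged within symmetric CG pairs **after** the coverage filter
  (whichever strands pass contribute), then unweighted across the annotated
  gene span; replicates pool weighted by site counts. Per-gene averaging is
  deliberately unweighted by coverage while replicate pooling is weighted —
  two different operations with different failure modes (deep sites should
  not dominate a gene; replicates with almost no sites should not dilute
  it). Genes with zero qualifying sites are NA, to be excluded explicitly.
* **TE distance**: 0 when a TE overlaps the annotated gene span (UTRs and
  introns count as genic), otherwise the number of bases strictly between
  the spans; strand ignored. The full gene span (not the CDS) is used
  because TEs inside UTRs/introns are the biologically salient case.
* **Clusters**: single-linkage chaining with an inclusive 50 kb gap;
  order-invariant; every gene lands in exactly one cluster or is a
  singleton. Neighbor pairs are two-member mixed clusters within an
  inclusive 2 kb gap (or directly adjacent in a supplied full annotation).

# Set statistics

The rank score ranks all genes of a sample ascending (mean ranks on ties)
and rescales the set's mean rank by the extreme achievable values, so 1
means "the set occupies the top m ranks". Permutation machinery:

* `perm_diff_test()` relabels by drawing |set| genes from the pooled
  genes; `matched_perm_diff_test()` stratifies the pool into covariate
  quantile bins (edges from the background distribution, default 10 bins)
  and resamples the set's per-bin composition — the standard reading of
  covariate-matched permutation; the bin count is exposed because the
  appropriate granularity depends on the covariate's dispersion. With one
  bin the matched test reduces exactly (same seed, same draws) to the plain
  test.
* Both the raw permutation p (which can be 0) and the add-one estimator
  (b+1)/(R+1) are reported; summaries use add-one. Sampling is without
  replacement; R defaults to 10,000.
* Reproducibility: one master seed per run, with per-test child streams
  derived deterministically (`derive_seed()`), so results do not depend on
  execution order.

Wilcoxon (exact only when the combined n <= 12 and tie-free), Kruskal–
Wallis, Fisher's exact test and BH adjustment are delegated to the standard
library implementations. BH correction is applied **within each family** of
tests (features, popgen, association, robustness, enrichment, tails), not
across the whole battery, mirroring how per-panel corrections are reported
in practice.

# The synthetic-data generator

The generator's defaults define the validation conditions and are not
tuned per run:

* **Set sizes**: 132 genes, 35 hv-like (the study's group sizes); 24
  accessions per clade.
* **Genealogy**: neutral coalescent with ms scaling — coalescence rate
  k(k−1)/2 in units of 4N generations, mutation count Poisson with mean
  (theta/2) x tree length — so E[pi] = theta and E[S] = theta·a1 hold
  exactly and calibration tests have closed-form targets. Infinite-sites
  collisions are re-drawn up to 100 times, then error.
* **Codon clades**: mutations propose uniform single-nucleotide changes;
  synonymous proposals always accepted, nonsynonymous with probability
  omega, stop-creating never (re-drawn). Omega is an acceptance
  probability, not a substitution-matrix likelihood: simple, monotone in
  realized piN/piS, sufficient for validation.
* **Diversity settings**: theta_low = 4, theta_high = 300 per gene
  (250 codons). The hv threshold demands >= 10 columns with three or more
  balanced amino-acid variants, which under a shared neutral genealogy
  requires recurrent nonsynonymous hits on internal branches;
  theta_high = 300 (~0.4/site) reproduces the near-saturated variability of
  genuinely hv receptor clades and yields >= 95% label recovery, while
  theta_low = 4 with omega = 0.2 never crosses the rule. These were fixed
  once from a pilot grid and are stated here as the package's definition of
  "hv-like" and "non-hv-like" simulation conditions.
* **Feature effects**: +2 log2 fold-change in expression (NB, mean 50,
  size 10, 4 replicates), CG methylation 60% vs 20% (Poisson coverage,
  mean 10, 30 symmetric CG pairs per gene, 2 replicates), TE overlap
  probability 0.6 vs 0.1 with exponential gaps (means 1 kb / 3 kb)
  otherwise; inter-gene gaps mix 5 kb (p = 0.3) and 80 kb so both clustered
  and singleton genes exist.
* **Determinism**: (config, seed) reproduces outputs bit-identically.

What the generator does **not** emulate: recombination within genes (one
genealogy per gene), selection acting on the genealogy itself (hv-likeness
is imposed via mutation supply and acceptance, not balancing selection),
demography, linked backgrounds between neighboring genes, TE families,
mappability artifacts, or bisulfite conversion error. Passing tests
therefore demonstrate that the estimators and tests are correct and
calibrated on data satisfying their assumptions — not that real NLR data
meet those assumptions.

# Validation problem sizes

The shipped test suite exercises: 2,000 coalescent replicates (n = 10,
theta = 5) for the pi/theta/D calibration; 200 clades per omega in
{0.1, 0.5, 1.0} (n = 8, theta = 20, 60 codons) for piN/piS monotonicity;
1,000 null data sets with R = 1,000 permutations each for the type-I
calibration of the plain and matched tests; and the full 132-gene default
configuration for label recovery. The acceptance script repeats the same
computations at 1,000/100/500 replicates. These sizes give Monte-Carlo
standard errors comfortably inside the asserted bands (e.g. ~0.007 on a
0.05 rejection rate at 1,000 simulations).

# Known limitations

* Heterozygous VCF genotypes are retained as two haplotypes; for outcrossing
  species a phasing-aware treatment would be needed.
* NG86 has no multiple-hit correction; at the simulator's hv-like mutation
  densities realized piN/piS compresses toward 1, which is why the
  monotonicity (not the absolute value) across omega is the tested
  contract.
* The Kruskal–Wallis robustness battery subsets only by cluster status;
  N-terminal domain classes are accepted as labels but no classifier is
  provided — they are inputs, as are domain annotations.
* The empirical-tail machinery assumes the background distribution is
  computed on the same statistic and length normalization as the gene set;
  the package does not check comparability beyond that convention.
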