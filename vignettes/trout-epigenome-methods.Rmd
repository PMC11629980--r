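---
title: "Methods: chromatin-state, super-enhancer, methylation and ohnolog-fate analysis"
author: "troutEpi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chromatin-state, super-enhancer, methylation and ohnolog-fate analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(troutEpi)
```

# Scope and model

`troutEpi` implements the downstream statistics of a functional-epigenome
annotation of rainbow trout (*Oncorhynchus mykiss*): a genome segmented per
tissue into ten chromatin states (two promoter states TssA/TssAFlnk, four
enhancer classes EnhG/Str.Enh/MidEnh/EnhPois, an accessible CpG state,
bivalent enhancers, polycomb-repressed and quiescent), together with
histone-mark peak calls, per-CpG bisulfite counts, TPM expression over six
tissues, QTL intervals for domestication traits, and ohnolog triplets left
by the salmonid-specific whole-genome duplication. Upstream steps — read
alignment, peak calling, ChromHMM training, collinearity and homology
search, motif discovery — are out of scope: segmentations, peaks, CpG
counts, QTL, motif occurrences and triplets are consumed as inputs.

All coordinates are 0-based half-open, the BED convention; GFF-style
1-based inputs must be shifted on read. Interval overlap is delegated to
`GenomicRanges`/`IRanges` behind a small data.frame-based surface
(`find_overlaps()`, `merge_intervals()`), and every test of that surface
carries an independent all-pairs brute-force oracle.

# Fold enrichment of states in elements

For a state and an element set, `fold_enrichment()` computes
$(C/A)/(B/D)$, with $A$ bases in the state, $B$ bases in the element set,
$C$ bases in their overlap and $D$ the genome size. Element intervals are
merged before $B$ and $C$ are counted: the statistic is a base count, so a
base covered by two overlapping element intervals must count once — this
also makes the result invariant to splitting elements into adjacent
pieces. A fold of 1 means no enrichment; when $A = 0$ or $B = 0$ the fold
is reported as `NA` rather than 0 or infinity so downstream summaries are
not poisoned. A seeded Monte-Carlo test places a state uniformly at random
1,000 times and checks that the mean fold lies in $[0.95, 1.05]$.

Density profiles around the TSS (`state_density_profile()`) average a
per-gene covered/not indicator per distance bin rather than raw base
counts, which normalizes gene count and matches how such panels are read;
bins are strand-aware (negative offsets upstream).

# Tissue specificity

`call_tissue_specific()` applies two rules: a gene is specific to a tissue
when its TPM is at least 10-fold the *sum* of its TPM in all other
tissues, or when its TPM is at least 1 and every other tissue is exactly
zero. The fold rule is scale-invariant and can fire in at most one tissue.
The same gene is treated as "silenced" in the remaining tissues, the
contrast set for the mark analysis: a mark counts for a gene when exactly
one tissue's peak set for that mark overlaps the ±3 kb TSS window
("uniquely exists", any-bp overlap), and counts are normalized by the
mark's genome-wide peak total in that tissue. The specific-versus-silenced
contrast is tested with a Pearson chi-square on the 2×2 count table, 1 df,
no continuity correction; peak counts (not gene counts) are the counting
unit, chosen as the literal reading of counting "marks".

Expression is log10-transformed with a pseudocount of 0.01 for zeros —
the plots include non-expressed genes and the source convention is
unstated, so one pseudocount is fixed and documented. Expression bins are
20 equal-width bins over the observed log10 range.

# Super-enhancers

`stitch()` clusters H3K27ac peaks whose nearest edges lie within 12.5 kb
(transitive closure), summing member signals; stitching is idempotent.
`call_superenhancers()` sorts clusters by ascending signal, scales both
rank and signal to $[0,1]$, and estimates the tangent slope of the scaled
curve by a *trailing* finite difference over a smoothing half-window of
$\max(1, n/100)$ ranks. The super-enhancer set is the clusters whose
scaled signal exceeds the scaled signal at the last rank with slope ≤ 1.

Two numerical choices matter here and were made deliberately. First,
trailing rather than central differences: a central difference at the last
conventional cluster looks across the cutoff into the super-enhancer tail
and inherits its slope, flagging one low-signal cluster too many (on
signals `1,1,1,1,100` it would flag two clusters where the curve clearly
has one outlier). Second, the cutoff is a *signal* threshold, not a rank
threshold, which is how the tangent construction on the ranked curve is
meant: everything above the signal where the curve last rises no faster
than the diagonal. On a perfectly linear curve the slope is 1 everywhere
and nothing is flagged; on all-equal signals the scaled curve is
degenerate and the caller warns and flags nothing. A consequence worth
knowing: a tied plateau of maximal signals has internal slope 0, so planted
super-enhancer signals in the generator escalate geometrically — which is
also what ranked H3K27ac curves of real tissues look like.

Cross-tissue merging is single-linkage with an overlap of at least 50% of
the *shorter* member (the more inclusive conventional reading; a
reciprocal mode is available). Genes are assigned to an SE when their body
extended by ±10 kb intersects it, annotated expressed (TPM > 2), repressed
(TPM < 0.2) or intermediate. Promoter-proximal peak exclusion is off by
default because the emulated protocol does not apply it.

# Methylation

The level of a CpG is C/(C+T). `filter_sites()` keeps sites with depth
≥ 10 and at or below the sample's 99.9th depth percentile, the standard
guard against PCR bias; the percentile is computed on the unfiltered
sample with linear interpolation (type-7), a convention fixed and
documented since the source does not state one. On integer sequencing
depths the tied values at the threshold make the filter idempotent in
practice, and the tests verify this on Poisson depths.

TSS meta-profiles average per-(gene, bin) first and across genes second,
so CpG-dense genes do not dominate (per-site averaging is available by
aggregating `per_gene` output directly). State-body profiles rescale each
instance's body to 20 bins with fixed-resolution 2-kb flanks.

# QTL, SNPs and motifs

Enhancer-state segments (EnhG, Str.Enh, MidEnh) intersecting QTL are
counted per (segment, QTL) pair with mean/median overlap lengths.
Per-chromosome enrichment uses the simplest null — expected counts
proportional to chromosome length — with a weight-vector mode (e.g. QTL
bases per chromosome) for alternatives; expected-weighted folds average
to 1 by construction. SNPs (1-based positions, VCF convention, converted
internally) are retained when they fall inside a QTL, an enhancer-state
segment and a motif occurrence simultaneously. Because real reports of
this analysis count at more than one dedup level, both the deduplicated
SNP count and the raw (SNP, QTL, segment, motif) hit count are returned;
the family summary is computed over unique (SNP, family) pairs. Motif
scanning itself is not performed — occurrences are inputs.

# Ohnolog retention fates

Absolute expression vectors are converted to relative profiles
(proportions of total expression; triplets with an all-zero member are
ineligible). For duplicates D1, D2 with ancestral proxy A,
$E_{D1,A}$, $E_{D2,A}$ and $E_{D1+D2,A}$ are Euclidean distances between
relative profiles, the combined profile being the relative profile of the
summed absolute vectors. The divergence cutoff is the median of
singleton-pair distances in the sister species plus the semi-interquartile
range, $(Q_3-Q_1)/2$, robust to outliers; quartiles use linear
interpolation (Tukey hinges by flag). One global cutoff is used — the
source compares against the singleton distribution through a single
SIQR-based threshold and gives no tissue-matched subsets. The rule table
(boundaries inclusive at the cutoff, matching the "≤" formulation):

| $E_{D1,A}$ | $E_{D2,A}$ | $E_{D1+D2,A}$ | fate |
|---|---|---|---|
| ≤ | ≤ | – | conserved |
| > | ≤ | – | neofunctionalized (D1) |
| ≤ | > | – | neofunctionalized (D2) |
| > | > | ≤ | subfunctionalized |
| > | > | > | specialized |

The rules partition all $2^3$ sign patterns; the direction of
neofunctionalization is kept internally and pooled for headline
proportions.

# Epigenetic divergence

Promoter profiles are built over the 2 kb immediately upstream of each
copy's TSS. Log2 fold-enrichment ratios are z-scored with the
*population* standard deviation — the formula defines δ without a Bessel
qualification, so the n-denominator is used and the output has mean 0 and
population sd exactly 1. Pair similarity is Pearson's r of the two
profiles with dissimilarity 1 − r; the default profile is a 10-bin
coverage vector per mark concatenated across marks, which preserves
spatial pattern (a per-mark scalar mode reproduces coarser analyses; the
source does not pin down whether correlations run across marks, bins or
pair sets, so the vector definition is the default and the others are
reachable by supplying the corresponding vectors). State-count vectors
count segments of each of the 10 states in the upstream window; shared
counts are per-state minima aggregated by fate. Category comparisons use
the Wilcoxon rank-sum test: exact enumeration for combined n ≤ 12 without
ties, otherwise midranks with normal approximation and continuity
correction.

# The synthetic-data generator

The generator is first-class, tested code: it emits every input the
pipeline reads, in the exchange dialects of the readers, with planted
ground truth sufficient to score every stage. Its defaults are the
emulated study conditions, fixed at design time:

* **Genome/genes** — 3 chromosomes × 2 Mb, 450 non-overlapping genes on
  both strands (desk-scale stand-ins for a 2.2-Gb genome; the tests that
  need other sizes say so explicitly).
* **States** — per-tissue complete tilings; dwell lengths default to the
  published per-state mean segment lengths (e.g. TssA 1,382 bp, ReprPC
  4,762 bp) with Quies shortened to 30 kb so that a 2-Mb chromosome still
  mixes states; coverage targets put ~77% of bases in Quies, and gap
  remainders too short for a full dwell draw are absorbed by Quies so the
  other states keep their planted length distribution. TssA (with
  TssAFlnk flanks) is planted at the TSS of genes expressed (TPM > 2) in
  that tissue and Str.Enh upstream of planted tissue-specific genes.
* **Expression** — log-normal TPM; 8% of genes planted tissue-specific
  under the calling rules themselves (three quarters by the 10-fold rule,
  one quarter by the ≥1-vs-all-zero rule), and every non-planted gene
  adjusted so neither rule fires: planted labels are exact truth.
* **Methylome** — background level 0.75, trough 0.10 at the TSS with a
  Gaussian shoulder (σ = 300 bp) centred 50 bp downstream of the TSS so
  the profile minimum falls unambiguously in the first downstream bin
  (biologically, the hypomethylated trough of CpG-island promoters sits
  at/just past the TSS); level capped at 0.5 inside active states; Poisson
  depth (mean 30) with 2% of sites planted below depth 10 and 15 extreme
  outliers to exercise both filters.
* **Triplets** — fate mix defaults to 73.6/14.2/0.2/12% (conserved/neo/
  sub/specialized); relative-profile noise is Gaussian on the simplex
  (clip at 0, renormalize), sd 0.02; neo/sub/specialized profiles are
  rejection-sampled to lie ≥ 0.35 from the ancestor, far above the
  singleton-derived cutoff (~0.08 at that noise), so planted labels are
  recoverable; subfunctionalized copies split the ancestor's absolute
  expression exactly, making the combined profile reproduce the ancestor
  at zero noise.
* **QTL/SNPs** — 12 QTL of 100–300 kb across three trait labels; 30% of
  300 SNPs planted inside enhancer∩QTL∩motif triples with motif families
  70% C/EBP / 30% GR (exact counts); the rest are negative controls of
  three kinds (outside QTL, in QTL but quiescent, in a QTL enhancer with
  no motif); decoy motifs sit outside QTL.

Every sub-generator runs on its own RNG stream derived from the master
seed, so stages are individually reproducible. What the generator does
*not* emulate: read-level noise, mappability and PCR artifacts, realistic
chromosome-scale heterogeneity, linkage between QTL and causal variants,
and the biological coupling between methylation, marks and expression
beyond the planted monotone trends. Passing tests therefore demonstrate
the correctness and calibration of the statistics, not that the biology of
any real tissue would reproduce specific published magnitudes — those
derive from billions of reads of real sequencing data.

# Problem sizes and determinism

The shipped tests run the interval oracle on 200 random instances (n, m ≤
200), the null calibration on 1,000 placements, specificity on 1,000
genes × 6 tissues, the methylome on 100,000 CpGs, fates on 1,000 triplets,
and divergence ordering on 500 pairs per category — sizes chosen so the
whole suite and the end-to-end run stay comfortably on one CPU while
keeping Monte-Carlo error well inside the asserted tolerances.
`run_pipeline()` re-runs byte-identically for a fixed seed; its manifest
records parameters and md5 checksums, not timestamps, precisely so that
reruns are comparable.

# Known limitations

* The tangent-slope cutoff is undefined on tied maximal signals (zero
  slope plateau); such data yield no super-enhancers rather than an
  arbitrary cut.
* The chi-square contrast offers peak counts only in its headline path;
  the gene-count variant is a one-liner on the returned per-mark counts
  but is not separately exposed.
* One global fate cutoff is used; tissue-matched singleton baselines are
  not implemented.
* Methylation profiles assume CpG context only; other cytosine contexts
  are out of scope.
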