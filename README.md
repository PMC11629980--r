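# troutEpi

Downstream analysis of a functional-epigenome annotation of rainbow trout
(*Oncorhynchus mykiss*), the partially tetraploid salmonid left by the
Ss4R whole-genome duplication. Given per-tissue chromatin-state
segmentations (10 states), histone-mark/ATAC peak calls, per-CpG bisulfite
counts, TPM expression over six tissues, QTL intervals and ohnolog triplet
tables, the package computes:

* **State enrichment** — base-level fold enrichment of a chromatin state
  in an element set, `(C/A)/(B/D)` with A = bases in the state, B = bases
  in the element, C = overlapping bases, D = genome size; per-state track
  summaries and TSS density meta-profiles.
* **Tissue specificity** — genes called specific when TPM is ≥ 10-fold
  the sum over all other tissues, or ≥ 1 TPM with all others zero; marks
  uniquely present at their ±3 kb TSS windows contrasted between specific
  and silenced tissues with a 2×2 Pearson chi-square; mark/state density
  versus log10 TPM with R².
* **Super-enhancers** — ROSE-style calling: peaks stitched within
  12.5 kb, stitched clusters ranked by H3K27ac signal, both axes scaled
  to [0,1], and the super-enhancer set taken above the point where the
  tangent slope of the ranked curve last drops to 1; nonredundant SEs by
  ≥ 50%-of-shorter single-linkage merging across tissues; gene assignment
  within ±10 kb with expressed (TPM > 2) / repressed (TPM < 0.2) classes.
* **Methylation** — per-CpG level C/(C+T); sites filtered at depth ≥ 10
  and ≤ the sample's 99.9th depth percentile; strand-aware TSS
  meta-profiles, scaled state-body profiles, and promoter
  methylation-versus-expression association.
* **QTL regulatory overlap** — enhancer-state × QTL overlap summaries,
  per-chromosome observed/expected fold enrichment, and the
  SNP ∩ QTL ∩ enhancer ∩ motif intersection with TF-family summaries.
* **Ohnolog retention fates** — relative expression profiles, Euclidean
  distances E(D1,A), E(D2,A), E(D1+D2,A) against an ancestral singleton
  proxy, a cutoff of median + semi-interquartile range over singleton-pair
  distances, and the four-way classification into conserved /
  neofunctionalized / subfunctionalized / specialized, plus promoter
  epigenetic divergence metrics (population-sd z-scores, Pearson r and
  1 − r, state-count correlations, Wilcoxon rank-sum comparisons).

A synthetic-data module generates every input with planted ground truth
(specificity labels, SE regions, methylation structure, SNP families,
fate labels), so the full pipeline is testable at desk scale without any
downloads.

## Worked example

```r
library(troutEpi)

cfg <- sim_config(seed = 1)          # 3 chromosomes x 2 Mb, 450 genes, 6 tissues
sim <- simulate_all(cfg)

# fold enrichment of each state in the ±2 kb TSS windows (first tissue)
tssw <- flank_tss(sim$genes, 2000, 2000, sim$genome)
enr <- fold_enrichment(sim$tracks[[1]], tssw[, c("chrom", "start", "end")],
                       sim$genome)
head(enr[order(-enr$fold), c("state", "fold")], 3)
#>      state     fold
#> 2 TssAFlnk 2.962591
#> 1     TssA 2.863593
#> 8   BivEnh 1.160354

# super-enhancers in brain from stitched H3K27ac clusters
se <- call_superenhancers(stitch(sim$peaks$brain$H3K27ac))
sum(se$is_super)
#> [1] 9

# retention fates of 1,000 ohnolog triplets
bl <- baseline_cutoff(singleton_distances(sim$triplets$s1, sim$triplets$s2))
cls <- classify_triplets(sim$triplets$d1, sim$triplets$d2,
                         sim$triplets$anc, bl$cutoff)
fate_proportions(cls$fate)
#>                fate   n proportion
#> 1         conserved 674      0.674
#> 2 neofunctionalized 196      0.196
#> 3 subfunctionalized   2      0.002
#> 4       specialized 128      0.128
```

The promoter states lead the enrichment ranking because the generator
plants them at the TSS of expressed genes (the fold stays modest at this
toy gene density, where TSS windows cover a third of the genome); the
fate proportions recover the planted mix (73.6/14.2/0.2/12%) up to the
configured profile noise. An end-to-end run over every stage, writing TSVs and a manifest
with parameter values and output checksums, is:

```r
run_pipeline(sim_config(seed = 1), "run1")
```

Reruns with the same seed are byte-identical.

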