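# driversub

Driver-gene-centred multi-omics subtyping of tumor cohorts.

Tumor cohorts are molecularly heterogeneous, and subtypes defined from a
single data layer are often unstable. `driversub` implements a subtyping
pipeline that starts from cancer driver genes and their family members and
integrates somatic mutations, expression, DNA methylation, miRNA, and copy
number into robust patient subtypes, together with a seeded synthetic
multi-omics cohort generator that plants known two-subtype structure in
every layer so the whole pipeline can be validated against ground truth.
It is aimed at computational biologists building or benchmarking
multi-omics stratification analyses.

## The method

**Stratification genes.** For each protein domain shared by a gene family,
the observed in-domain mutation count is compared with a permutation null
in which each gene's mutations are re-placed uniformly over its protein
(p-value `(#{permuted ≥ observed} + 1)/(n_perm + 1)`, BH-adjusted). The
dispersion of a domain's mutations across its n carrier genes is scored
with the normalized entropy

&nbsp;&nbsp;&nbsp;&nbsp;S = −Σᵢ Pᵢ ln Pᵢ / ln n,

where Pᵢ is gene i's share of the domain's mutations: S = 1 for uniform
family-wide dispersion, S = 0 when one gene holds them all. Genes mutated
in a significant, high-entropy (S > 0.5) domain become *stratification
genes*. Hypermutated samples (TMB > 30 mutations/Mb, TMB = nonsilent
count / 38 Mb) are excluded first.

**Driver-dysregulated genes (DDGs).** Family genes differentially
expressed between tumor and normal (Mann–Whitney U, BH < 0.05,
|log₂FC| > 1, mean ≥ 1) are kept as DDGs when their dysregulation is
supported by correlated evidence (Spearman |ρ| > 0.2, BH < 0.05) from a
differentially methylated probe (|Δβ| > 0.2), a differentially expressed
miRNA targeting them, or a copy-number gain/loss group (|CNV| > 1 in >20%
of samples).

**Subtype recognition.** The patient × stratification-gene binary matrix
F₀ is smoothed over a gene-interaction network by propagation

&nbsp;&nbsp;&nbsp;&nbsp;F_{t+1} = α F_t A + (1 − α) F₀,  α = 0.7,

iterated until the Frobenius norm of the step is below 10⁻⁶ (A is the
row-stochastic network operator). The smoothed profiles and z-scored
log₂(x+1) DDG expression are fused by similarity network fusion (K = 20
neighbors, bandwidth 0.5, 20 diffusion rounds) into one patient similarity
W, which is clustered by subsampled consensus clustering (maxK = 6,
5000 repetitions, 80% item sampling, Spearman distance, average linkage).
The cluster count k maximizes the mean silhouette
`sil(i) = (b(i) − a(i))/max(a(i), b(i))` on D = max(W) − W, and subtypes
are named CLASS A, CLASS B, … by descending size.

**Characterization and classification.** Subtypes are contrasted by
chromosomal instability (CIN ratio = arms with |score| > 0.1 / total
arms), mutation association (chi-square, or Fisher's exact when expected
counts fall below 5), and Kaplan–Meier/log-rank survival. A subtype
classifier panel is selected by strict differential expression
(BH < 0.001, |log₂FC| > 1), a mean-interval filter (subtype intervals
[μ−σ, μ+σ] must be disjoint), and elastic-net regularization; the final
SVM is trained on a stratified 70/30 split with cross-validated grid
search and reported as ACC/SEN/SPE/MCC. Pseudo-bulk profiles (per-sample
sums of single-cell counts) can be classified directly.

## Worked example

```r
library(driversub)
res <- run_demo(seed = 1)   # synthetic cohort, demo profile
print(res)
#> <pipeline_result>
#>   stratification genes: 23 | DDGs: 40 | chosen k: 2
#>   ARI vs planted truth: 0.934
#>   panel size: 20 | held-out ACC: 0.972 MCC: 0.946
print(res$classifier$metrics)
#> TP=17 TN=18 FP=1 FN=0 | ACC=0.9722 SEN=1.0000 SPE=0.9474 MCC=0.9459
res$survival_test$p_value
#> [1] 8.9e-05
```

The demo generates a 120-sample cohort with two planted subtypes, three
mutation-hotspot domains, and 40 planted differential genes. The pipeline
recovers 23 stratification genes (the mutated hotspot-family members; the
planted low-entropy decoy domain is rejected by the entropy filter), all
40 planted genes as DDGs, chooses k = 2, reassembles the planted labels
with adjusted Rand index 0.93, and separates survival (log-rank
p ≈ 9×10⁻⁵; planted hazard ratio 2). The classifier panel attains
held-out accuracy 0.97.

Each stage is exported on its own (`test_domain_burden()`,
`assemble_ddgs()`, `propagate()`, `snf_fuse()`, `consensus_cluster()`,
`train_and_evaluate()`, …) and runs on files in plain tab-separated
formats; `write_cohort()`/`run_pipeline(list(input_dir = ...))` exercise
the full file interface. A thin command-line wrapper lives at
`inst/cli/driversub.R`.

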