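---
title: "driversub: models, parameters, and numerical conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{driversub: models, parameters, and numerical conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the scientific model behind `driversub`, every
tunable parameter that matters, the design of the synthetic validation
cohort, and the numerical conventions the implementation commits to.
It states no empirical result beyond what the package's test suite and
`scripts/acceptance.R` themselves compute.

# The subtyping model

## Domain mutation burden and the entropy filter

The pipeline's premise is that informative stratification features come
from driver genes and their family members, and specifically from protein
domains that concentrate mutations. For a domain carried by a gene family
the test asks: is the observed number of in-domain mutations larger than
expected if each gene's mutations were placed uniformly over its protein?

The null is simulated per gene: a gene with $m_g$ observed mutations and a
domain covering $r_g$ of its $L_g$ residues contributes a permuted
in-domain count distributed as $\mathrm{Binomial}(m_g, r_g/L_g)$ — exactly
the distribution of placing $m_g$ mutations independently and uniformly
with replacement, which is how the implementation draws it (a direct
binomial draw rather than materializing positions; the distribution is
identical and the run is far cheaper). The domain statistic sums carriers,
and

$$p = \frac{\#\{\text{permuted} \ge \text{observed}\} + 1}{n_{\text{perm}} + 1},$$

so $p$ is never 0 and never below $1/(n_{\text{perm}}+1)$. Ties count
against the observation (conservative). Benjamini–Hochberg correction is
applied across all tested domains; the number of permutations defaults to
9999 (resolving $p$ to $10^{-4}$), 999 in the demo profile.

Significance alone does not distinguish a family-wide mutational
mechanism from a single dominant gene. The dispersion of a domain's
mutations across its $n$ carriers is scored with the normalized entropy
$S = -\sum_i P_i \ln P_i / \ln n$, where $P_i$ is carrier $i$'s share.
Conventions: $0 \ln 0 = 0$; a single-carrier domain ($n = 1$) has
$S = 0$ by definition, because the $\ln 1$ denominator is degenerate and a
lone carrier offers no family-dispersion evidence; a zero-count domain
returns a flagged missing value. *Stratification genes* are the genes
with at least one mutation inside an instance of a domain that is both
significant (adjusted $p < 0.05$) and dispersed ($S > 0.5$, strict).

Upstream sanitation keeps only point mutations in protein space
(missense, nonsense, splice), drops positions beyond the protein, and
excludes hypermutators: TMB = nonsilent mutations / 38 Mb, with samples
strictly above 30 mutations/Mb removed (a sample at exactly 30 stays).

## Driver-dysregulated genes

Differential calls use the Mann–Whitney U test (normal approximation
with tie and continuity correction — sample sizes here make exact
enumeration pointless), BH correction, fold change
$\log_2((\bar{x}_{\mathrm{test}}+1)/(\bar{x}_{\mathrm{ctrl}}+1))$ on the
raw scale, thresholds $|\mathrm{log_2FC}| > 1$, adjusted $p < 0.05$, and a
mean-abundance floor of 1 in at least one group. Methylation probes are
called differential at $|\Delta\beta| > 0.2$; gene-level copy number
forms gain/loss groups when strictly more than 20% of samples exceed
+1 / fall below −1.

A family DEG becomes a *driver-dysregulated gene* when at least one
regulatory layer co-varies with its tumor expression: an annotated DMP
(promoter / gene body / distal enhancer), a differentially expressed
miRNA listed as targeting it, or its own CNV score — each screened by
Spearman correlation at $|\rho| > 0.2$ with BH-adjusted $p < 0.05$,
corrected within its evidence batch (methylation pairs together, miRNA
pairs together, CNV pairs together; the correction family is otherwise
arbitrary and this choice keeps batches comparable in size). Evidence
combination is a **union** across layers: requiring all three would
restrict DDGs to genes measured and perturbed in every layer, which is
not what the integration is after; a config switch
(`ddg_combine = "intersection"`) provides the strict variant. No sign
constraint is placed on $\rho$ — promoter methylation usually
anti-correlates, but the direction is reported rather than enforced so
users can filter.

## Subtype recognition

The binary patient × stratification-gene matrix $F_0$ (presence, not
multiplicity) is smoothed over a gene-interaction network:

$$F_{t+1} = \alpha F_t A + (1 - \alpha) F_0, \qquad \alpha = 0.7,$$

iterated from $F_0$ until the **Frobenius** norm of the step drops below
$10^{-6}$ ("matrix norm" is otherwise ambiguous; Frobenius makes the stop
rule a plain Euclidean criterion). $A$ is the **row-stochastic**
normalization $A_{ij} = w_{ij}/\sum_j w_{ij}$ restricted to the genes of
$F_0$; a gene with no surviving edge receives a self-retention row
($A_{ii} = 1$). Row-stochasticity makes $F A$ an averaging operator, so
each patient's total mutation mass is conserved — an invariant the test
suite checks to $10^{-9}$ — and the fixed point has the closed form
$(1-\alpha) F_0 (I - \alpha A)^{-1}$, which the tests verify to
$10^{-8}$ on random networks. $\alpha = 1$ is rejected (no fixed point).
An optional rank-based quantile normalization across patients after
smoothing is exposed (`quantile_normalize`), default off: the subtype
model here feeds the smoothed matrix directly into fusion rather than
into a factorization, and rank-flattening the profiles discards the
burden differences the fusion can use.

Expression enters as $z$-scores of $\log_2(x+1)$ per gene, using the
population standard deviation (divisor $n$); zero-variance genes become
all-zero with a warning rather than NaN.

Similarity network fusion follows the published cross-diffusion scheme:
per layer, Euclidean sample distances; a scaled-exponential kernel whose
local bandwidth averages each sample's mean distance to its $K = 20$
nearest neighbors, scaled by $\mu = 0.5$ (the "variance of the local
model"); half-mass row normalization that pins every sample's
self-similarity at $1/2$ during diffusion; a $K$-NN-sparsified transition
kernel; and $T = 20$ rounds of cross-layer diffusion, averaging the
diffused layers into the fused $W$ (symmetrized, strictly positive
diagonal). One numerical guard is added: the local bandwidth is floored
at 1% of the layer's mean off-diagonal distance. Without it, exactly
duplicated profiles — routine in sparse binary mutation data, where many
samples share an all-zero row — collapse the bandwidth to machine
epsilon, giving those samples effectively infinite mutual affinity that
no amount of cross-layer diffusion can temper; the floor lets genuinely
identical samples remain maximally similar while keeping the kernel
finite. With a single layer the procedure reduces to that layer's own
diffusion limit.

Consensus clustering subsamples $\lceil 0.8 n \rceil$ samples for each of
5000 repetitions (500 in the demo profile), represents each sample by its
row of $W$ restricted to the subsample, clusters
$1 - \mathrm{Spearman}$ row correlations by average-linkage hierarchical
clustering, and cuts at each $k = 2..6$. Consensus is the co-clustered
fraction among co-sampled pairs; never-co-sampled pairs (probability
negligible at these settings, counted and warned) get 0. Final labels per
$k$ come from average-linkage clustering of $1 - M_k$. Subsampling is the
only seeded randomness; hierarchical clustering ties are resolved by the
deterministic input ordering.

Model selection converts similarity to distance as
$D = \max(W) - W$ with a zero diagonal (the simplest monotone inversion;
the silhouette only uses distance ratios) and picks the $k$ maximizing
the mean silhouette $\mathrm{sil}(i) = (b_i - a_i)/\max(a_i, b_i)$;
singleton clusters score 0. Because $W$'s diagonal dominates its
off-diagonal entries after fusion, silhouette values on this $D$ are
compressed toward 0 — their *ranking* across $k$, not their magnitude,
carries the information. Clusters are renamed CLASS A, CLASS B, … by
descending size; the convention is arbitrary but deterministic.

## Characterization and the classifier

CIN ratio: arms with score strictly above 0.1 or strictly below −0.1
count as altered; the ratio divides by the arms actually scored (missing
arms leave numerator and denominator). Mutation–subtype association uses
the chi-square test with continuity correction for 2×2 tables,
substituting Fisher's exact test when any expected cell is below 5 (the
standard switching rule; the choice only matters for rare features).
Survival separation uses the standard log-rank test and Kaplan–Meier
medians (first time the estimate reaches ≤ 0.5; missing when never
reached).

Classifier candidates are subtype DEGs at the stricter
BH $< 0.001$, $|\mathrm{log_2FC}| > 1$. The mean-interval filter then
keeps genes whose subtype intervals $[\mu - \sigma, \mu + \sigma]$ of
$\log_2(x+1)$ expression are disjoint; intervals sharing an endpoint
count as overlapping (the conservative reading), and $\sigma$ is the
sample standard deviation (divisor $n-1$). Note the deliberate asymmetry
with the fusion $z$-score above: each operation follows its own stated
convention, fixed here once. Elastic-net regularization
(`glmnet`, $\alpha_{\mathrm{EN}} = 0.5$, $\lambda$ by stratified
cross-validation at `lambda.min`) selects the panel — its size is
data-driven, not forced to a target; if every coefficient vanishes the
full interval-pass set is returned with a warning. The SVM (linear
kernel, `e1071`) is trained on a stratified 70% split with the cost
chosen by stratified 5-fold grid search over $2^{-3..3}$ on the training
split only; panel expression is standardized with the training set's
per-gene center and scale, and the same transformation is applied at
prediction time — including to pseudo-bulk profiles, which are plain
per-sample sums of single-cell counts. Metrics are ACC, SEN, SPE, and
MCC; MCC is reported unscaled in $[-1, 1]$ (0 when its denominator
vanishes).

# The synthetic cohort

`generate_cohort()` plants a complete two-subtype ground truth so every
stage can be validated against known labels. Reference conditions
(defaults of `synthetic_cohort_config()`):

| parameter | default | meaning |
|---|---|---|
| `n_samples` | 120 | tumor samples, subtype B fraction 0.5 |
| `n_families` × `members_per_family` | 10 × 6 | families; one shared 50-aa domain each (proteins 500 aa) |
| `n_background_genes` | 140 | genes outside families |
| `n_hotspot_domains` | 3 | domains with subtype-B in-domain mutations, Poisson mean 0.8/sample, allocated uniformly across members (high entropy) |
| `background_mutation_rate` | 0.05 | per sample × gene, uniform position |
| `n_planted_degs`, `deg_log2fc` | 40, 2 | subtype-B expression shift on the log2 scale, noise sd 0.5 |
| `meth_effect_delta_beta` | 0.3 | promoter β drop in tumors (plus B-modulation of a third of it) |
| `mirna_target_rho` | −0.7 | planted miRNA–target anti-correlation strength |
| `cnv_arm_instability_prob_B` / `_A` | 0.4 / 0.1 | per-arm alteration probability (39 autosomal arms) |
| `hazard_ratio_B`, `median_survival_A_months` | 2, 20.55 | exponential survival; exponential censoring at 0.02/month (~30% censored) |
| `network_within_family_p` / `_background_p` | 0.4 / 0.02 | edge probabilities |

Design notes:

* **Evidence planting.** Planted DEGs cycle through the three evidence
  modalities. Because differential methylation and differential miRNA are
  called *tumor vs normal* while the Spearman evidence runs *within*
  tumors, the planted shifts have two parts: a tumor-wide component that
  makes the probe/miRNA differential, and a subtype-B modulation that
  creates the within-tumor correlation with the (B-shifted) target
  expression. Beta values are clipped to $[0, 1]$ and expression to
  $\ge 0$ after noise.
* **Decoy domain.** One extra domain always concentrates its planted
  mutations in a single family member: it reaches burden significance but
  has entropy near 0, exercising the dispersion filter.
* **Survival** is exponential so the median and hazard ratio are in
  closed form; the subtype-A median (20.55 months) is a typical
  advanced-HCC scale.
* **Null switch.** `null_cohort_config()` zeroes every planted effect
  (no hotspot/decoy mutations beyond background, no expression or
  evidence shifts, equal arm probabilities, hazard ratio 1) for
  calibration and false-positive checks; the explicit
  `cnv_arm_instability_prob_A` field exists so the arms can be equalized.

What the generator does **not** emulate: mutational signatures and
position-specific hotspots within a domain, batch effects and cohort
mixtures, expression–methylation coupling beyond the planted monotone
links, copy-number segment structure (gene scores are independent), and
non-proportional hazards. Passing the planted-recovery tests therefore
shows the pipeline's machinery is correct and calibrated under the
assumed generative structure — not that it will resolve subtypes in any
particular real cohort.

# Validation problem sizes

The test suite runs the full pipeline on the default 120-sample cohort
across 10 seeds with 500 consensus repetitions (demo profile), checks
permutation calibration on 500 simulated null domains at
$n_{\mathrm{perm}} = 999$, verifies the propagation closed form on 20
random 20-gene networks, checks null cohorts across 5–10 seeds at 250
consensus repetitions, and evaluates log-rank type-I error over 500 null
simulations. These sizes were chosen as the smallest at which the
binomial/analytic tolerances in the tests are meaningful.

# Known limitations

* Consensus clustering stores one $n \times n$ consensus matrix per
  candidate $k$; cohorts beyond a few thousand samples would need a
  sparser accumulator.
* The Mann–Whitney p-values use the normal approximation throughout;
  for groups under ~8 samples an exact test would be preferable.
* The permutation test treats residues as exchangeable within a protein;
  codon-level mutability differences are out of scope.
* The silhouette model-selection criterion inherits the compressed scale
  of $D = \max(W) - W$; comparisons *across* runs of the mean silhouette
  are not meaningful, only the per-run choice of $k$.
* `filter_and_impute()`'s KNN imputation is $O(\text{features}^2)$ over
  features with missing data; methylation arrays with hundreds of
  thousands of sparse probes would need a neighbor index.
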