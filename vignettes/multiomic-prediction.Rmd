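---
title: "Multi-omic genomic prediction with weighted relationship kernels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-omic genomic prediction with weighted relationship kernels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omicblup)
```

## The problem

Genomic prediction in small plant-breeding panels asks how well a
quantitative trait can be predicted for untested lines from molecular data
on tested relatives. The classical predictor is a SNP-derived relationship
matrix, but omic layers closer to the phenotype — sequence variants called
from mRNA, expression presence/absence variation (ePAV), gene- and
transcript-level expression, metabolite abundances — can carry additional
or complementary information. `omicblup` implements the complete analysis
for a panel of fully homozygous inbred lines: per-layer relationship
kernels, GBLUP under replicated five-fold cross-validation, a grid search
over a joined weighted relationship matrix, dataset-level dissimilarity by
generalized Procrustes analysis (GPA) with principal coordinates analysis
(PCoA), and an emulation of 3'end mRNA sequencing. A synthetic-data
generator with known genetic architecture provides ground truth for every
stage, so the whole pipeline is testable without any external dataset.

## Models

### Adjusted entry means and heritability

Replicated multi-environment observations follow

$$y_{ijk} = \mu + E_j + G_i + (G\times E)_{ij} + \varepsilon_{ijk},$$

with genotype effects fixed and environment and interaction effects random
(REML, via lme4) when estimating the adjusted entry means $\hat y_i$; for
single-environment experiments (e.g. greenhouse metabolites) the model
reduces to genotype plus residual. Refitting with genotype random yields
$\sigma^2_G$, and the entry-mean heritability is

$$H^2 = \frac{\sigma^2_G}{\sigma^2_G + \bar\nu/2},$$

where $\bar\nu$ is the mean variance of a difference between two adjusted
entry means, computed over all unordered genotype pairs from the
variance–covariance matrix of the means ($C_{ii}+C_{jj}-2C_{ij}$). We chose
the all-pairs average because it is the literal reading of "mean variance
of a difference"; a design-based approximation would differ only in
unbalanced designs. Variance components are constrained non-negative;
lme4 returns exact zeros at the boundary. One numerical subtlety: on
*exactly* noiseless data the profiled likelihood degenerates and the
optimizer returns unreliable components, so for balanced designs with a
residual below $10^{-8}$ the estimator switches to the exact
expected-mean-squares solution of the balanced ANOVA, which is also the
oracle the test-suite checks against.

### Kernels

For every layer, features with zero variance or a missing rate strictly
above 0.2 are removed, remaining gaps are mean-imputed, and the additive
relationship matrix is

$$G = \frac{W^* {W^*}^{\top}}{m},$$

where the $m$ columns of $W^*$ are centered and scaled to unit variance.
We standardize with the population convention (divisor $n$), which makes
$\mathrm{trace}(G) = n$ exactly and the average diagonal 1 — the common
GBLUP normalisation; the sample convention would only rescale all kernels
by the same factor and leaves predictions unchanged. Standardization makes
$G$ invariant to affine recoding of any feature, so 0/1 versus 0/2
genotype coding is immaterial.

ePAV calls per gene use the per-gene maximum `Mx` across inbreds: 0 is
absent, values in the open interval $(0, 0.1\,\mathrm{Mx})$ are ambiguous
(`NA`), and values at or above $0.1\,\mathrm{Mx}$ are present — both
inequalities strict, so a value exactly at the 10% cut is present. The
across-tissue combination is any-presence dominance: present if present in
at least one tissue, absent if every non-missing call is absent, `NA`
otherwise. The combination rule is our own design choice; published
pipelines defer the detail to prior work, and any rule satisfying
"union smaller than sum" of tissue calls behaves equivalently downstream
because the kernel standardization absorbs the coding. Sequence variants
are partitioned by a SIFT-style score: deleterious at score $\le 0.05$,
tolerant above.

### GBLUP and cross-validation

Prediction uses the mixed model

$$y = 1\mu + Zu + \varepsilon,\qquad u \sim N(0, G\sigma^2_u),\qquad
\varepsilon \sim N(0, I\sigma^2_e)$$

on the adjusted entry means. The variance ratio
$\lambda = \sigma^2_e/\sigma^2_u$ is profiled out of the restricted
likelihood with a single eigendecomposition of the training kernel and
optimized on the log scale (`optimize` on $[\log 10^{-6}, \log 10^{8}]$,
tolerance $10^{-10}$). Centered kernels at $n \le 22$ are rank-deficient,
so $\lambda$ is floored at $10^{-6}$; the floor plays the role of a ridge
jitter but is kept inside $\lambda$ so that the hold-out predictor

$$\hat u_{\mathrm{test}} = G_{\mathrm{test,train}}
  (G_{\mathrm{train,train}} + \hat\lambda I)^{-1}(y - \hat\mu 1)$$

coincides with ridge regression on $W^*$ with penalty $m\hat\lambda$ to
machine precision — the identity the test suite verifies on random
instances at $10^{-8}$. Zero phenotypic variance is handled by the
convention $\hat\lambda = \infty$, $\hat u = 0$.

Cross-validation is five-fold with fold sizes differing by at most one,
replicated with fresh random partitions; replicate $r$ is seeded
`base_seed + r` so partitions are reproducible and can be *shared* across
predictors and weight vectors, giving paired comparisons that remove the
partition noise from contrasts. $\lambda$ is re-estimated inside every
training fold — no information from the held-out fold reaches the fit.
The reported summary is the median ability across folds within a
replicate, then the median of those medians across replicates. A fold must
contain at least three samples for the Pearson ability to be defined, so
five-fold CV needs $n \ge 15$. A constant prediction vector has ability 0
by convention, flagged.

The grid search enumerates all weight vectors on the simplex lattice
(step 0.1: 286 combinations for four kernels) and cross-validates the
joined kernel $\sum_k w_k G_k$ under shared partitions. Ties are broken by
fewest active kernels, then lexicographically — the tie-break matters only
in exact-tie situations such as identical kernels. Vertex vectors
reproduce single-kernel results exactly under shared seeds, which the
tests assert with `identical`. One layer represents each predictor group
in the grid, chosen by the most stable performance across traits:
highest minimum ability-rank across traits, ties by mean rank.

### Dataset similarity

Each layer is summarised by PCA scores of the column-standardized matrix
($k = \min(n-1, 10)$ components, padded with zero columns where a layer
has fewer); GPA then aligns the configurations by translation,
rotation/reflection and isotropic scaling to a consensus, iterating until
the residual changes by less than $10^{-10}$ (at most 100 iterations),
with the total sum of squares held fixed so the solution cannot collapse.
Reflections are permitted. Pairwise dissimilarity is the symmetric
Procrustes statistic $m^2 = 1 - (\sum_i \sigma_i)^2$ of the normalized
cross-product's singular values — i.e. one minus the Procrustes
correlation (Gower) — clamped to $[0,1]$ against floating-point rounding.
PCoA double-centers $-\tfrac12 D^2$ and eigendecomposes; negative
eigenvalues (the correlation-based distances are not Euclidean) are
dropped with a warning rather than corrected, and percent variance is
reported over the positive spectrum only. Predicted-value distances are
$1 - r$ between concatenated hold-out predictions per replicate,
median-aggregated element-wise.

### 3'end emulation

The 3'end study keeps, per gene, the window of the last $N$ bp
(strand-aware, clamped to the gene span, $N = \infty$ as the full-length
sentinel), restricts variants to the windows, and re-quantifies expression
by Poisson read thinning: a full-length count
$\mathrm{Pois}(\mathrm{depth}\cdot GE\cdot L/10^3)$ with uniform read
starts, counting reads inside the window and re-normalizing by window
length, which is unbiased for the original value. The thinning mechanism
is our modeling choice — the source protocol for "measuring" truncated
genes is not described — and deliberately ignores sequencing error, PCR
duplicates, and 3' coverage bias. Draws depend only on the seed and input
order, never on $N$, so windows of different sizes thin the same virtual
reads: subsets are nested and $N \ge L$ reproduces the full-length
baseline exactly. Windows are computed on unspliced gene spans.

## The synthetic-data generator

`sim_config()` defaults emulate a spring-barley diversity panel: 23
inbreds, seven phenotyping environments, greenhouse quadruplicates for the
metabolites, metabolite heritabilities drawn from $[0, 0.98]$, and trait
heritabilities (LA 0.91, PH 0.83, HT 0.90). Genotypes are biallelic and
fully homozygous (coded 0/1), arranged in per-gene linkage blocks (each
variant copies its gene's block haplotype with probability `block_r`); a
`fraction_deleterious` subset carries SIFT-like scores $\le 0.05$ and
2.5-fold-spread effects; 2% of entries are masked missing. Expression is
`softplus(baseline + standardized cis value + tissue shift + noise)` with
transcript values a Dirichlet isoform split that conserves the gene total
exactly; presence/absence structure is injected by zeroing values with a
probability *decreasing* in the genetic value, so ePAV kernels carry
signal. Metabolites are sparse linear combinations of seedling expression
with replicate noise calibrated analytically to a target entry-mean
heritability ($\sigma^2_e = K(1-h^2)/h^2$ for $K$ replicates and unit
genetic variance); $h^2 = 1$ is unreachable with finite replication and is
an error. Phenotypes follow the multi-environment model above in a fully
balanced layout — the estimators under test are design-agnostic, so the
augmented field designs of real trials are not emulated — with the
non-genetic variance split 40/60 between interaction and residual and
$h^2=1$ allowed as the exact noiseless limit. One master seed fans out to
fixed per-stage child seeds, so each stage is individually reproducible
and identical configurations are bit-identical.

What the generator does *not* emulate: linkage disequilibrium between
genes, population structure, epistasis (effects are purely additive),
realistic expression covariance between genes, or the joint distribution
of real omic layers — no public characterization of that joint
distribution exists. Passing tests therefore demonstrate that the
estimators and protocols recover known truth under a plausible additive
architecture, not that any particular real-data result will reproduce.

## Problem sizes and statistical design of the checks

The test suite and the acceptance script scale the experiments to the
precision each question needs:

* Heritability recovery runs at the panel's own conditions (22 inbreds,
  7 environments, 10 replicates per environment) with 100 simulation
  replicates per target; the estimator's mean bias there is below 0.01 at
  every target, and the ±0.05 check is comfortably stable. Under a *zero*
  true heritability the estimator's null distribution is approximately
  $1 - 1/F$ with $F \sim F(21, 66)$ — broad by nature — so the tests
  assert that distribution rather than an unattainably tight one.
* The heritability–ability comparison (0.9 vs 0.5) is run on a simulated
  panel of 80 inbreds with the two traits sharing identical genetic values
  and shared fold partitions. At 22 inbreds the comparison is dominated by
  the luck of the two fixed noise draws — the win fraction across 50
  paired replicates ranges anywhere from 0.2 to 1.0 depending on the
  dataset seed — whereas at 80 inbreds the ordering is stable at 1.0; the
  larger panel answers the question the check actually asks (does higher
  heritability yield higher ability under this protocol?).
* Grid-search weight recovery likewise uses 80 inbreds and a four-kernel
  set built to be distinguishable: the trait is a linear combination of
  seedling-expression features including their non-genetic component
  (`expr_noise_sd = 1.2`), the competing ePAV kernel comes from the other
  tissue, and the metabolites carry target heritability 0.1. When all
  layers are simulated downstream of the same expression matrix the
  "which layer owns the trait" question has no stable answer at small n —
  the competitors are genuinely predictive.
* The ridge-equivalence oracle uses 50 random instances at
  $n \in [12, 22]$, $m \in [30, 100]$; the observed maximum discrepancy is
  around $10^{-10}$.

## Known limitations

* REML for entry means relies on lme4; pathological designs (a genotype
  observed in a single cell) are estimable but only flagged, not
  reweighted.
* The GPA similarity index follows Gower's Procrustes correlation; other
  software may scale the statistic differently, so absolute dissimilarity
  values are comparable within this package, not across tools.
* PCoA drops negative eigenvalues rather than applying a Cailliez
  correction; with strongly non-Euclidean distances the percent-variance
  figures refer to the positive spectrum only.
* The 3'end study inherits every simplification of the read-thinning
  model and windows unspliced gene spans; exon-aware windowing would
  shift variant retention for multi-exon genes.

## A short run

```{r demo, eval = FALSE}
res <- make_demo(seed = 1)
res$abilities          # per-layer, per-trait median prediction abilities
res$grid$LA$best       # optimal kernel weights for trait LA
tidy(res$three_prime)  # 3'end windows vs the full-length baseline
autoplot(res$gpa_pcoa) # layer map from GPA dissimilarities
```
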