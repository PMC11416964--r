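---
title: "Genomic prediction for hybrid breeding: models, simulator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic prediction for hybrid breeding: models, simulator and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`hybridgp` implements the genomic-selection workflow used in hybrid crop
breeding: genotype a panel of inbred parent lines once, phenotype a modest
sample of their F1 crosses, fit an additive whole-genome regression, and
then predict the genetic merit (GEBV) of *every* possible cross so that
the breeder can choose which hybrids to actually make. This vignette is
the package's account of the underlying models, the synthetic population
the package validates itself on, and the numerical and design choices
that were genuinely open.

## The additive model and its two ridge solvers

All parametric machinery rests on the mixed model

$$ y = \mu + Z u + e, \qquad u \sim N(0, I\sigma_u^2), \quad
   e \sim N(0, I\sigma_e^2), $$

where $Z$ is the $n \times m$ matrix of training-hybrid allele dosages
(columns centered by their training means) and $u$ the vector of additive
marker effects. The BLUP solution is the ridge estimate

$$ \hat u = Z^\top (Z Z^\top + \lambda I)^{-1} (y - \hat\mu),
   \qquad \lambda = \sigma_e^2 / \sigma_u^2, $$

computed through the $n \times n$ dual system because training sets
(hundreds to ~2000 hybrids) are far smaller than marker panels (tens of
thousands of SNPs). The dual and primal forms are algebraically identical
(Woodbury identity); the test suite enforces agreement to $10^{-8}$ on
random instances, along with the GBLUP duality
$\hat g = \hat\mu + K_{cn}(K_{nn} + \lambda I)^{-1}(y - \hat\mu)$ for
kinship-form prediction.

The two methods differ only in how $\lambda$ is chosen:

* **rrBLUP** (`fit_rrblup()`): by default $\lambda$ comes from a
  single-component REML fit on the training kinship ($h^2 \mapsto
  \lambda = \bar c\,(1-h^2)/h^2$, with $\bar c$ the mean diagonal of
  $Z_c Z_c^\top$, which maps the variance ratio onto the centered-dosage
  solver). A 10-fold cross-validated grid search
  (`lambda_strategy = "cv_grid"`, 25 points log-spaced around the marker
  count, ties broken toward stronger shrinkage) is available as the
  protocol-style alternative; both are offered because published
  descriptions of rrBLUP's "cross-validated" ridge parameter are rarely
  precise, while canonical implementations actually use REML.
* **HEBLP|A** (`fit_heblp_a()`): $\sigma_u^2$ is estimated by
  Haseman–Elston regression on an IBS-derived relationship matrix and
  $\lambda = (1-\sigma_u^2)/\sigma_u^2$ on the standardized phenotype
  scale, then rescaled by the same $\bar c$. The HE slope is clamped to
  $[0.01, 0.99]$ before the ratio is formed so $\lambda$ stays finite;
  a clamp is recorded on the model and signalled as a warning.

Intercept handling is deliberately minimal: $\hat\mu$ is the training
phenotype mean and no further fixed effects are modeled, matching how
these predictors are used in single-environment hybrid trials. Marker
columns are centered but not variance-scaled inside the solver — scaling
differences are absorbed by $\lambda$. If the dual system is numerically
singular (e.g. $\lambda \to 0$ with duplicated training rows) the solver
retries once with a $10^{-8}\,\bar c$ jitter.

## Relatedness, and why the package rescales it

Two similarity matrices drive variance-component estimation:

* the **GRM** (`compute_grm()`), VanRaden-scaled:
  $G = W W^\top / m$ with $w_{ik} = (z_{ik} - 2p_k)/\sqrt{2p_k(1-p_k)}$
  at observed allele frequencies;
* the **IBS matrix** (`compute_ibs()`):
  $\mathrm{IBS}_{ij} = 1 - \overline{|z_i - z_j|/2}$ over
  pairwise-complete markers.

Both estimators (`he_regression()`, `reml_heritability()`) normalize
their input to unit mean diagonal before estimating. This matters on
fully inbred panels: with homozygous dosages the VanRaden diagonal is
$\approx 1 + F \approx 2$, and without the normalization $\sigma_g^2$
and $h^2$ are reported at half their per-individual value. On hybrid
populations (diagonal $\approx 1$) the normalization is a no-op.

Raw IBS needs one more step before its HE slope can be read as a
variance: two *unrelated* lines still share alleles by chance, so IBS
lives on a compressed absolute scale. `ibs_to_relationship()` applies
the affine map $r = (\mathrm{IBS} - (1-b))/b$, where the baseline
dissimilarity $b$ is the mean over markers of $E|x - x'|/2$ for two
independent draws from the marker's empirical dosage distribution. The
map sends the expected unrelated pair to 0 and the no-missingness
diagonal to 1; without it the HE slope is inflated by roughly
$1/(2\bar p \bar q)$ and truncates at 1.

## Heritability estimators

* `he_regression()`: ordinary least squares of the pair products
  $y_i y_j$ (phenotypes standardized) on the normalized relatedness
  entries over all $i<j$; the slope is $\hat\sigma_u^2 = \hat h^2$ on
  that scale, clamped to $[0,1]$ with a flag, and the raw slope is kept
  for diagnostics.
* `reml_heritability()`: single-component REML for
  $y = 1\mu + g + e$, $g \sim N(0, \sigma_g^2 G)$, via one
  eigendecomposition of $G$ and a bounded golden-section search over
  $h^2 \in [10^{-6}, 1-10^{-6}]$ (tolerance $10^{-6}$); the total
  variance is profiled out analytically, and components are reported on
  the observed phenotype scale.

Calibration, measured by the acceptance suite on unstructured panels of
500 inbred lines with 1000 markers and 200 QTL averaged over 20
architectures, is within $\pm 0.1$ of the target for
$h^2 \in \{0.1, 0.5, 0.9\}$ for both estimators, and the HE slope on
pure noise is centered at zero.

A caveat the package makes no attempt to hide: on a *single* strongly
stratified population (e.g. one draw of the three-group hybrid study),
moment-based HE estimates have large architecture-to-architecture
variance, because the realized between-group genetic variance rests on
only a couple of group contrasts — one random projection of the QTL
effects that no amount of markers averages away. REML, which whitens by
the full covariance model, is far more stable there and is the method
of record for per-trait heritability; HE's role is fast shrinkage
selection inside HEBLP|A, where ridge prediction is forgiving of a
misjudged $\lambda$.

## The synthetic breeding population

No genotypes or phenotypes ship with the package, so validation runs on
a simulator (`simulate_study()`) built to emulate the study design this
pipeline targets:

* **Founders** (`simulate_founders()`): fully homozygous inbred lines
  (dosage 0/2) in named germplasm groups. Allele frequencies follow the
  Balding–Nichols construction — ancestral frequency uniform on
  $[0.1, 0.9]$, group frequency Beta-distributed with mean $p$ and
  variance $F p(1-p)$. One parameter ($F$, default 0.2) controls group
  separability; real residual heterozygosity is ignored in simulation
  (the data path accepts dosage 1 throughout). Optional uniform
  missingness masks calls.
* **Architecture** (`simulate_qtl_effects()`): a QTL subset of markers
  with i.i.d. normal effects, rescaled so the founder genetic-value
  variance is exactly 1 — heritability then controls the noise exactly
  and all acceptance tolerances are scale-free.
* **Hybrids and phenotypes** (`make_hybrid_genotypes()`,
  `simulate_hybrid_phenotypes()`): hybrid dosage is the parental mean
  (exact for inbred parents), phenotype = genetic value + group-pair
  shift + Gaussian noise of variance $\sigma_g^2(1-h^2)/h^2$. Phenotypes
  exist only for hybrids, as in the target breeding design.
* **Heterotic structure**: `group_shift` plants additive shifts per
  unordered group pair. A *pure* one-category jump is a non-additive
  effect that an additive GEBV model can only partially express (its
  best additive approximation recovers roughly half of such a jump), so
  the end-to-end validation plants an additive-consistent germplasm
  boost — $+\delta$ for crosses within the favored group, $+\delta/2$
  for crosses with one parent in it — i.e. heterosis expressed as
  group-level combining ability. Under that planting the pipeline
  recovers the category gap within a few hundredths of a unit against
  ground truth (tolerance $0.25\,\delta$ in the acceptance suite), where
  "ground truth" includes the architecture's own random category
  baseline, not just the planted shift.

What passing these tests does *not* show about real data: the simulator
has no dominance or epistasis, no genotype-by-environment structure, no
linkage map (markers are exchangeable), and missingness is uniform
rather than platform-structured. Results on traits with substantial
non-additive variance (the situation where ensemble methods catch up
with the ridge family) are exercised only qualitatively, via the
delegated random-forest and gradient-boosted-tree baselines.

## Filters, imputation and file formats

Marker retention (`filter_hybrid_markers()`) applies three rules in
order, with drop attribution to the first failure: (a) at least two
distinct non-missing genotype classes, (b) missing fraction ≤ 0.3,
(c) minor-allele frequency ≥ 0.1 among non-missing calls — thresholds
exposed as arguments. "Genotype classes" means the dosage categories
0/1/2, and frequencies are computed over non-missing calls at the locus;
filters are applied to the parental matrix, and hybrid construction
commutes with marker subsetting. Missing dosages are marker-mean imputed
(`impute_missing()`) before any model fitting; observed entries are
never touched, so column means are preserved exactly.

Genotypes read/write as minimal VCFv4.2 (GT field, biallelic; dosage =
ALT-allele count; multiallelic records dropped with a count) or as a TSV
dosage table; phenotypes as CSV; relatedness as square TSV; trees as
Newick; models as JSON.

## Diallel prediction, GCA, heterotic patterns

`enumerate_crosses()` lists the half-diallel ($N(N-1)/2$ unordered
pairs, no selfs, lexicographic canonical order).
`predict_all_crosses()` materializes hybrid genotypes only in batches
(default 2000 crosses), so a 360-line diallel (64,620 crosses) never
holds more than one batch in memory, and batching provably does not
change a single GEBV. Selection summaries use
`top_fraction()` (size $\lfloor f \cdot N_\text{crosses} \rfloor$, ties
at the boundary broken by canonical pair order),
`genetic_gain()` (top-fraction mean minus overall mean — non-negative
and non-increasing in the fraction), and `gca()` — defined, as breeders
use it here, as a line's mean GEBV over its $N-1$ crosses, not the
classical least-squares diallel decomposition. The mean of all GCAs
equals the overall cross mean exactly, a conservation identity the
tests enforce at $10^{-12}$. `heterotic_summary()` reports, per
unordered group-pair category ($k(k+1)/2$ of them for $k$ groups),
count, mean and sd of GEBV, plus top-fraction composition and the share
of top crosses with at least one parent per group. GEBVs keep the
intercept, so summaries are on the trait scale rather than as centered
deviations.

## Germplasm grouping

`p_distance_matrix()` is the complement of IBS similarity.
`nj_tree()` wraps Saitou–Nei neighbor joining (exact on additive tree
metrics — the suite regenerates random trees up to 8 leaves and demands
topology and path lengths back to $10^{-10}$); negative branch lengths
on non-additive inputs are kept as computed and flagged, never clamped,
precisely so that exactness test is meaningful. Group assignment
(`assign_groups()`) cuts an average-linkage hierarchical clustering of
the distance matrix into $k$ groups (labels ordered by cluster size for
determinism) — chosen over a tree-cut rule because no principled cut
height exists for these data; curated labels via `load_groups()` are
the primary path for real analyses. Balanced-minimum-evolution tree
building was deliberately not reimplemented: the tree's role here is
visual confirmation of cluster structure, and NJ is deterministic,
dependency-light and exact where exactness can be checked.

## Evaluation protocol

`evaluate_methods()` repeats random train/candidate splits
(`make_splits()`, replicate $r$ seeded `seed + r`), fits every requested
method on the identical training set within a replicate (paired
comparison), and scores the Pearson correlation between candidate
phenotypes and predictions (`accuracy()`). Per-trait missingness is
handled by dropping records for that trait only, which is why candidate
sets can differ in size across traits at a fixed training size. The
summary reports mean ± standard error over replicates
($\mathrm{sd}/\sqrt{R}$; a single replicate reports 0 with a flag), and
`correlate_h2_accuracy()` gives the heritability–accuracy correlation
with a t-based p-value.

## Problem sizes used in validation

The shipped suites size their simulations as follows, chosen once as
realistic desk-scale stand-ins for the motivating study (360 lines,
33k SNPs, 2077 phenotyped hybrids): heritability recovery at $n = 500$
lines × 1000 markers × 20 replicates; protocol properties at 150
founder lines × 1000 markers with 1000 phenotyped hybrids (800 train /
200 candidate) × 10 replicates per heritability level; end-to-end boost
recovery at 150 lines × 2000 markers × 10 seeds; the acceptance script
runs one full-size 360-line study (groups 90/164/106, 2077 phenotyped
hybrids, 2000 markers, 5 evaluation replicates) and predicts all 64,620
crosses. The script's demo simulates complete post-QC genotypes
(no residual missingness), keeping all dosages integer so the
indicator-product IBS fast path applies at $n = 2077$; missingness
handling is exercised by the unit suites.

## Known limitations

* Additive GEBVs only: no dominance or specific-combining-ability
  decomposition, no multi-trait index.
* HE-based shrinkage inherits moment-estimator instability under strong
  stratification (see above); the clamp plus ridge robustness contain,
  but do not remove, the effect.
* The MAF filter can drop genuinely causal rare markers; SNP
  heritability is then attenuated by the untagged fraction, as with any
  SNP-based estimator.
* No bootstrap support on trees, no model-based ancestry estimation;
  `assign_groups()` is a convenience, curated germplasm labels are
  preferred.
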