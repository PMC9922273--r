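---
title: "Methods: a simulation-tested proteogenomic pipeline for CSF aptamer proteomics"
author: "proteoMR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a simulation-tested proteogenomic pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proteoMR)
```

# Scope and model

proteoMR implements the statistical backbone of a proteogenomic cohort
study of a cerebrospinal-fluid (CSF) aptamer proteome with matched
genotypes: cis-pQTL mapping, two-sample Mendelian randomization (MR) with
Bayesian colocalization against external GWAS summary statistics,
subcohort-stratified differential protein expression, and hypothesis-free
stratification of idiopathic patients into proteomic endotypes with a
clinical prediction tree. Because the real individual-level data of such
studies are access-restricted, every stage is exercised against a
synthetic cohort generator with full ground truth; the package's tests
are therefore statements about the statistical behaviour of the methods
(calibration, power, parameter recovery, stability), not about any
particular cohort.

# The synthetic cohort generator

`sim_config()` fixes the study conditions; `simulate_cohort()` draws a
complete cohort from them. The generator emulates the *structure* of a
multi-centre proteogenomic study:

* **Genotypes.** Biallelic dosages on one synthetic chromosome, drawn by
  a Gaussian copula: a latent AR(1) process per LD block (correlation
  `ld_rho`, default 0.8, blocks of 10 variants) is thresholded at the
  allele-frequency quantile per haplotype, giving Hardy-Weinberg
  genotypes whose dosage correlation decays within blocks and is exactly
  zero across blocks. Variants sit at uniform 50-kb spacing so a ±1 Mb
  cis window holds a predictable ~40 variants. Minor allele frequencies
  are uniform on [0.1, 0.5], comfortably above the MAF > 0.05 instrument
  rule.
* **Sample metadata.** Six subcohort/status cells (idiopathic patients,
  healthy controls, GBA+ and LRRK2+ patients with matched unaffected
  carrier controls) at proportions mirroring a three-subcohort design;
  age, sex, centre and plate assignments; a medication flag for
  genetic-subcohort patients only — idiopathic patients are drug-naive.
* **Proteome.** Log2-scale analyte abundances: baseline + small
  age/sex/centre effects + a cis dosage effect for a configurable
  fraction of analytes (`prop_cis_regulated`, default 0.3; effect sd 0.5
  log2 per allele, or a fixed magnitude for power studies) + two planted
  co-expression modules + plate batch effects (additive location shifts,
  sd 0.3, and multiplicative noise-scale factors, log-sd 0.1, the
  location/scale model that empirical-Bayes batch correction assumes) +
  heteroskedastic Gaussian noise. Residual sds are lognormal across
  analytes (median ~0.4, log-sd 0.3): aptamer panels are strongly
  heteroskedastic, and homogeneous variances would make variance
  moderation degenerate.
* **GWAS summary statistics.** Rather than simulating the external
  cohort's individuals, marginal per-variant slopes are computed
  analytically from the generative model (`b_j = sum_k alpha_k
  cov(x_j, x_k) / var(x_j)`, with the dosage covariances taken from the
  genotype panel and cross-block covariance exactly zero) and perturbed
  with sampling noise at the configured GWAS size (default 5×10^5). This
  runs in milliseconds at any `gwas_n`. A fraction of cis-regulated
  proteins is causal for the trait (`theta_causal`, default 0.15 per
  protein-SD); the `"shared"` scenario routes the trait effect through
  the protein's own cis variant, the `"distinct"` scenario places it on a
  variant of the same region in a different LD block — the two
  colocalization hypotheses H4 and H3. Optional allele swapping and the
  naturally occurring palindromic allele pairs exercise harmonization.
* **Clinical variables.** For idiopathic patients, CSF p-tau is
  log-normal with endotype-conditional means straddling the 11 pg/mL
  boundary (endotype 1 ≈ 14, endotype 2 ≈ 8.7 pg/mL); amyloid-beta,
  total tau and alpha-synuclein are shifted down and UPDRS part I up in
  endotype 2; MoCA carries no endotype signal. `shift_scale = 0` gives a
  null cohort, `noise_scale` shrinks the within-endotype spread (a
  near-zero value yields a perfectly separable scenario for sanity
  checks).

## The endotype geometry, and what it implies

The two planted modules are latent-factor blocks (loadings 0.6–0.9)
sized at 19% and 13% of the panel, the proportions of the two modules
observed on a full ~4800-aptamer panel. Both factors shift between the
two endotypes of idiopathic patients. The shift (3.5 factor-sd units,
`endotype_sep`) was fixed once from a stability analysis of this
geometry: the patient clusters it produces are as stable under consensus
resampling as the endotypes reported for the real cohort (whose tracking
plot shows essentially no reassignment across k). At separations below
~2.5 the achievable adjusted Rand index is capped near 0.85 by genuine
boundary overlap and average-linkage clustering degenerates, which is
not the regime the observed data occupy.

One structural consequence is worth knowing: because both modules track
the endotype, their factors are correlated (about 0.75 at the default
separation), so an *unsigned* network frequently reports them as one
merged module at synthetic scale. The merged module still contains
exactly the planted module analytes and none of the background, and
patient clustering is unaffected. Multi-module recovery per se is tested
on planted-partition data with independent factors.

What the generator does **not** emulate: realistic human LD maps,
imputation uncertainty, sex chromosomes, relatedness, population
stratification, non-Gaussian assay artefacts, missing values, or
longitudinal visits. Passing tests therefore demonstrate correctness and
calibration of the machinery under a plausible generative model, not
robustness to every pathology of real data.

# Preprocessing

`log2_median_normalize()` equalizes each sample's median signal within
each dilution group to the group median, on log2 scale.

`combat_adjust()` is the canonical parametric empirical-Bayes
location/scale batch adjustment: per-analyte standardization against a
grand mean plus covariate fit, per-batch location (gamma) and scale
(delta^2) estimates, normal and inverse-gamma priors moment-matched
across analytes, and the conditional posterior means iterated to
convergence (tolerance 1e-6, at most 200 iterations) before
back-transforming. Biological covariates passed to the function are
protected; a design in which a covariate is confounded with batch is
refused, as are singleton batches. The tests verify agreement with the
reference implementation in the `sva` package to 1e-6. Note that
empirical-Bayes shrinkage makes the adjustment *contractive* rather than
exactly idempotent: the posterior mean removes a fraction
`n tau^2 / (n tau^2 + delta^2)` of each batch offset, so a second pass
changes the data by an order of magnitude less than the first but not by
zero. The practically relevant guarantees — residual batch-mean
difference below 0.01 log2 units at cohort scale while a planted 0.5
log2 disease effect is preserved within 5% — are asserted directly.

`compute_pcs()` returns column-centred SVD scores with a deterministic
sign convention; the default downstream designs use protein PCs 1–4.
PCs are computed after batch correction. `inverse_normal_transform()` is
the Blom rank transform `qnorm((r - 3/8)/(n + 1/4))` with average ranks
for ties (offset configurable); `bh_fdr()` is Benjamini-Hochberg.

# cis-pQTL mapping

A variant is cis to an analyte when it lies within ±1 Mb of the encoding
gene (boundaries inclusive, window clamped at position 1; analytes whose
aptamer targets several genes take the union of windows).
`scan_pqtl()` regresses every INT-transformed analyte on every cis
variant's dosage, adjusted for covariates (age, sex, subcohort, protein
PCs 1–4 and genetic PCs in the standard design), via Frisch–Waugh
residualization: both analytes and dosages are residualized on the
covariate design once, and each pair then reduces to a simple
regression with residual degrees of freedom `n - rank(design) - 1`.
This is algebraically identical to per-pair OLS (verified to 1e-8 over
100 random configurations) at a fraction of the cost. Variants with
MAF ≤ 0.05 are excluded; significance is the genome-wide `p < 5e-8`
with a strict inequality.

# Mendelian randomization

Instruments per protein are cis variants with MAF > 0.05, F > 10
(`F = (beta/se)^2`), and `p < 5e-8`, harmonized to the outcome GWAS
(sign flips for swapped alleles; palindromic variants kept only when
both allele frequencies are outside the 0.42–0.58 ambiguity band and
oriented by frequency side), then greedily LD-clumped at `r^2 < 0.3`
(in-sample dosage correlation; 0.01 available as the stringent
setting). A single surviving instrument gives the Wald ratio
`beta_out/beta_exp` with first-order SE `se_out/|beta_exp|`; two or
more give the inverse-variance-weighted mean of the per-variant ratios,
with the fixed-effect SE inflated by `max(1, sqrt(Q/(k-1)))`
(multiplicative random effects; Cochran's Q reported). The second-order
Wald SE and fixed-effect IVW are available behind flags.

Horizontal pleiotropy is tested with a simulation-based global
residual-sum-of-squares test: observed
`RSS = sum_j w_j (beta_out_j - beta_loo(-j) beta_exp_j)^2` with
leave-one-out IVW predictions and weights `1/se_out^2`, against a null
distribution obtained by re-drawing both sides from their standard
errors under the leave-one-out fitted model;
`p = (1 + #{RSS* >= RSS}) / (1 + n_sim)`. The test needs at least three
instruments — with fewer, the leave-one-out prediction is a single
ratio and the statistic is uninformative, so `NA` is reported. BH FDR
across proteins defines causal candidates at FDR ≤ 0.05.

Under the default conditions the tests verify |bias| < 0.05 for
theta in {0, 0.15, 0.3}, 95% CI coverage in [0.92, 0.975], pleiotropy
type-I error in [0.03, 0.08] at alpha = 0.05 and ≥ 90% power against one
gross outlier instrument.

# Colocalization

Each protein's cis region is colocalized with the outcome GWAS under
the single-causal-variant model with Wakefield approximate Bayes
factors, `log ABF = 0.5 log(V/(V+W)) + W z^2 / (2(V+W))`, prior effect
sd 0.15 for the quantitative pQTL trait and 0.2 for the case-control
outcome, and priors `p1 = p2 = 1e-4`, `p12 = 1e-5`. All hypothesis
weights are accumulated in log space with log-sum-exp — z^2 in the
thousands is routine — and `PPH4 > 0.75` flags strong colocalization.
The cross-term `L3` is computed as `log1p(-exp(gap))` on the log scale
and clamps tiny negative round-off at zero; with a single shared variant
it is exactly zero. Simulated shared-causal-variant regions give median
PPH4 > 0.75 and distinct-variant regions median PPH3 > PPH4.

# Differential expression

All per-analyte linear models share one QR decomposition of the design
(`fit_linear_models()`). Variance moderation follows the standard
empirical-Bayes formulation: a scaled inverse chi-square prior
moment-matched on the log-variance scale (digamma/trigamma moments,
Newton inversion of the trigamma function), posterior variances
`(d0 s0^2 + d s^2)/(d0 + d)`, and t-statistics on `d0 + d` degrees of
freedom. When the observed spread of log-variances is within sampling
noise the prior df is infinite and the common variance is the
arithmetic mean of the observed ones (complete pooling, with a
warning). The implementation is cross-checked against `limma` in the
test suite but not backed by it.

`run_comparisons()` runs the five standard models — GBA+ patients vs
GBA+ controls, LRRK2+ vs LRRK2+ controls, idiopathic vs healthy
controls, all patients vs all controls (adding mutation status and
treatment as covariates), and the disease-by-mutation interaction
(a moderated F test on the two interaction coefficients) — each
adjusted for age, sex, centre and protein PCs, with treatment included
only where patients can be treated. Case is coded 1, so positive log2
fold changes mean higher in patients. FDR is applied within each
comparison family, matching how such results are reported
per-comparison.

# Endotype discovery

The idiopathic patients' proteome is residualized on age, sex and
centre; co-expression structure is summarized by the unsigned
topological overlap matrix of `|cor|^power` with the soft threshold
fixed at 11 (the full-panel setting; `pick_soft_threshold()` provides
the scale-free diagnostics that motivate such a choice). Modules are
average-linkage clusters of `1 - TOM` under a static cut at
dissimilarity 0.99: uncorrelated analytes have topological overlap near
zero and merge at height ~1, so they dissolve, while genuine modules
merge far below the cut. (A cut at a *quantile* of the merge heights
does not work here — the top merges of a TOM dendrogram sit at ~1.0, so
any high quantile swallows the whole tree.) The minimum module size is
500 at full panel scale and adapts as `max(15, 0.1 x analytes)` on
smaller panels, preserving the ~10%-of-panel intent.

Patients are consensus-clustered on the module analytes: 100 subsamples
of 80% of patients, hierarchical clustering (Euclidean, average
linkage) per subsample, co-clustering proportions per pair restricted
to co-sampled replicates (extra replicates are drawn in the rare event
a pair was never co-sampled), final labels per k from clustering
`1 - consensus`, and the consensus-CDF Delta-area criterion reported
per k. k = 2 is the default carried into clinical characterization, and
on the synthetic cohorts the Delta-area criterion selects it.
A k-means inner loop is a possible alternative; the hierarchical inner
loop is the default because it matches the canonical consensus
clustering procedure.

Endotypes are characterized clinically with a chi-squared test for
categorical variables (Fisher's exact fallback when an expected count
drops below 1), a Gaussian GLM adjusted for age and sex for
quantitative variables, and a Mann-Whitney U test for age itself.
`protein_score()` computes externally weighted linear scores (the
weights of published proteomic risk scores are inputs, not outputs, of
this package).

`train_endotype_tree()` fits a CART classifier (Gini impurity, via
`rpart`) on clinical predictors only, using a stratified 70/30
train/test split and cost-complexity pruning by 10-fold
cross-validation with the one-standard-error rule. Two numerical
choices matter here. First, the CV error curve of a single 10-fold run
is noisy enough that its argmin frequently lands on a spurious subtree
under the null; the pruning therefore averages the CV curves of 7
repeated runs before applying the 1-SE rule, which makes a
label-independent predictor collapse to the root reliably while leaving
real splits untouched. Second, test AUC is computed from leaf class
proportions by the rank (Mann-Whitney) identity, since a pruned tree
only provides piecewise-constant scores. On the default synthetic
cohorts the tree recovers a single p-tau split near 11 pg/mL with test
accuracy around 0.8 — the regime reported for the real cohort — and on
a separable scenario it recovers the cutoff exactly with accuracy 1.

# Problem sizes, determinism, degenerate inputs

The shipped tests and the acceptance script use desk-scale cohorts —
300–1200 samples, 40–1000 variants, 10–280 analytes, 100–500 simulation
replicates per property — chosen so the full suite runs in about a
minute while every assertion retains comfortable statistical margin.
Every stochastic stage takes an explicit seed and is bit-reproducible;
the generator derives independent sub-seeds per stage so stages can be
re-run in isolation. Degenerate inputs are refused loudly rather than
patched silently: constant vectors in the INT, nonpositive raw
intensities, singleton or confounded batches, rank-deficient designs,
monomorphic variants (skipped and logged), zero exposure betas in the
Wald ratio, disjoint coloc regions, constant analytes in the network.

The interface of the package is its exported functions plus the TSV/VCF
writers (`write_cohort_tsv()`, `write_genotype_vcf()`,
`write_pqtl_tsv()`, `write_endotype_tsv()`, `write_gwas_tsv()`); the
result tables are plain data frames that `write.table()` exports.

# Known limitations

* Single-causal-variant colocalization only; no multi-signal (SuSiE-type)
  extension, no conditional analysis.
* MR estimators are Wald ratio and IVW, as in the motivating analysis;
  MR-Egger, weighted median/mode and Steiger filtering are out of scope.
* The pleiotropy test implements the global RSS test; outlier removal is
  limited to an optional leave-worst-out re-estimate.
* Trans-pQTLs, conditional/secondary cis signals, and real annotation
  (the aptamer-to-gene coordinate map is required input) are out of
  scope.
* The generator's LD and effect-size distributions are scenario
  parameters, not estimates of any real cohort.
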