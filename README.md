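# proteoMR

An R package implementing the statistical pipeline of proteogenomic
cohort studies of a cerebrospinal-fluid (CSF) aptamer proteome with
matched genotypes — the kind of study that maps protein quantitative
trait loci (pQTLs) in CSF, asks which proteins are *causal* for a
neurodegenerative disease via Mendelian randomization against an
external GWAS, contrasts patient subcohorts, and stratifies idiopathic
patients into molecular endotypes. It is written for methodologists and
analysts who need the full chain to be runnable, testable and
calibrated without access to restricted cohort data: a synthetic cohort
generator with complete ground truth stands in for the real thing.

## What it computes

* **Preprocessing** — median normalization by dilution group on log2
  scale; parametric empirical-Bayes batch (plate) correction
  (location/scale model, conjugate shrinkage, iterated posterior
  means); principal components; Blom inverse-normal transform;
  Benjamini–Hochberg FDR.
* **cis-pQTL scan** — every analyte against every variant within ±1 Mb
  of its encoding gene, adjusted for covariates via Frisch–Waugh
  residualization (exactly per-pair OLS, scanned in one pass);
  MAF > 0.05 filter; genome-wide significance `p < 5e-8`.
* **Two-sample MR** — instruments with F > 10 and `p < 5e-8`, allele
  harmonization (palindromes resolved by allele frequency), greedy LD
  clumping at `r² < 0.3`; the Wald ratio `β_GWAS/β_pQTL` for a single
  instrument, inverse-variance-weighted meta-analysis with
  multiplicative random-effects inflation otherwise; a simulation-based
  global horizontal-pleiotropy (RSS) test; FDR across proteins.
* **Colocalization** — Wakefield approximate Bayes factors,
  `log ABF = ½ log(V/(V+W)) + Wz²/(2(V+W))`, five-hypothesis posteriors
  with priors `p1 = p2 = 1e-4`, `p12 = 1e-5`, all in log space;
  `PPH4 > 0.75` flags a shared causal variant.
* **Differential expression** — shared-QR linear models per analyte,
  empirical-Bayes moderated t (log-scale moment matching with trigamma
  inversion), five subcohort comparisons including a disease×mutation
  interaction F test, FDR within each comparison.
* **Endotypes** — residualize on age/sex/centre, unsigned topological
  overlap matrix at soft threshold 11, static-cut module detection,
  consensus clustering of patients (subsampling, co-clustering
  proportions, Δ-area criterion), clinical characterization
  (chi-squared / adjusted GLM / Mann-Whitney), and a cost-complexity
  pruned CART tree (70/30 split, repeated 10-fold CV, 1-SE rule)
  predicting endotype from clinical variables only.
* **Synthetic cohorts** — LD-blocked copula genotypes, a structured
  log2 proteome (cis effects, covariates, plate batches, two
  endotype-coupled co-expression modules, heteroskedastic noise),
  analytically generated GWAS summary statistics with shared/distinct
  causal-variant scenarios, and endotype-conditional clinical variables
  (p-tau straddling 11 pg/mL). Everything is seed-deterministic and
  ground truth is returned alongside the data.

## Worked example

```r
library(proteoMR)

cfg <- sim_config(n_samples = 500, n_variants = 300, n_analytes = 80,
                  cis_effect_dist = "fixed", seed = 3)
coh <- simulate_cohort(cfg)

norm <- log2_median_normalize(coh$proteome)
bm   <- combat_adjust(norm$values, coh$meta$plate,
                      covariates = data.frame(status = coh$meta$status,
                                              age = coh$meta$age))
pcs  <- compute_pcs(bm$corrected, 4)
Y    <- apply(bm$corrected, 2, inverse_normal_transform)

win  <- map_cis_windows(coh$proteome$analytes, coh$genotypes$variants)
scan <- scan_pqtl(Y, coh$genotypes,
                  data.frame(age = coh$meta$age, sex = coh$meta$sex,
                             sub = coh$meta$subcohort, pcs), win)
significant_cis_pqtls(scan)
#> cis-pQTL hits at p < 5e-08: 72 records over 24 analyte(s)

mr <- run_mr(scan, coh$gwas, coh$genotypes, n_presso_sim = 200, seed = 5)
mr
#> MR causal table: 24 proteins, 7 causal candidate(s) at FDR <= 0.05
#>   analyte_id n_instruments     method   beta       fdr pleiotropy_p ...
#> 1    apt0030             1 Wald ratio 0.1192 2.96e-219           NA
#> 2    apt0055             3        IVW 0.0893  5.31e-99        0.751
#> 3    apt0067             1 Wald ratio 0.1034  7.22e-88           NA
#> ...

coloc_posteriors(scan[scan$analyte_id == "apt0030", ], coh$gwas)
#> coloc over 40 variants: PPH0=0.000 PPH1=0.000 PPH2=0.000 PPH3=0.000
#> PPH4=1.000  [strong colocalization]
```

The MR table mirrors the usual reporting shape (instrument count,
method — Wald ratio iff a single instrument survived clumping — causal
effect per protein-SD, FDR, global pleiotropy p, reported only from 3
instruments). The top candidates include all five proteins the
generator made causal, plus neighbours picked up through LD with a
causal variant — the classic cis-MR false-positive mode — and the
shared-causal-variant region colocalizes at PPH4 ≈ 1. On the endotype
side:

```r
cfg2 <- sim_config(n_samples = 600, n_variants = 200, n_analytes = 150, seed = 11)
coh2 <- simulate_cohort(cfg2)
bm2  <- combat_adjust(coh2$proteome$values, coh2$meta$plate,
                      covariates = data.frame(status = coh2$meta$status))
ef   <- discover_endotypes(bm2$corrected, coh2$meta, seed = 4)
ef
#> endotype_fit: 185 idiopathic patients, 48 module analytes in 1 module(s)
#>   endotype sizes: 102 / 83

idio <- match(ef$sample_ids, coh2$meta$sample_id)
tree <- train_endotype_tree(coh2$meta[idio, c("ptau","abeta","ttau","asyn",
                                              "updrs1","moca")],
                            ef$labels, seed = 9)
tree
#> endotype_tree: 1 split(s); accuracy train 0.791 / test 0.821; test AUC 0.819
#>   primary split: ptau at 10.82
```

The consensus clusters recover the planted endotypes (the two planted
modules are reported as one merged module here — both track the
endotype strongly, so an unsigned network cannot separate them; see the
methods vignette), and a single p-tau split near the 11 pg/mL boundary
predicts them from clinical data alone at ~0.8 accuracy — the
qualitative behaviour this class of study reports.

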