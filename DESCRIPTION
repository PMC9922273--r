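Package: proteoMR
Title: Proteogenomic Analysis of a CSF Aptamer Proteome: cis-pQTL Mapping,
    Mendelian Randomization, Colocalization, Differential Expression and
    Endotype Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, simulation-testable pipeline for proteogenomic
    cohort studies of cerebrospinal-fluid aptamer proteomics. Provides
    median/log2 normalization and parametric empirical-Bayes batch
    correction; rank-based inverse normal transforms; covariate-adjusted
    cis-pQTL scans over +/-1 Mb gene windows via Frisch-Waugh
    residualization; two-sample Mendelian randomization (Wald ratio and
    inverse-variance-weighted estimators) with instrument selection,
    allele harmonization, greedy LD clumping and a simulation-based global
    horizontal-pleiotropy test; Bayesian colocalization with Wakefield
    approximate Bayes factors; moderated-t differential expression across
    disease subcohorts with interaction models; weighted co-expression
    networks (soft-thresholded unsigned topological overlap), consensus
    clustering of patients into proteomic endotypes, and a pruned
    classification tree predicting endotype from clinical variables.
    Includes a synthetic cohort generator (LD-blocked genotypes,
    cis-regulated log2 proteome with plate batches, analytic GWAS summary
    statistics, endotype-structured clinical variables) with full ground
    truth so every stage is testable without access to restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    rpart
Suggests:
    testthat (>= 3.0.0),
    limma,
    sva,
    mclust,
    jsonlite
Config/testthat/edition: 3
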