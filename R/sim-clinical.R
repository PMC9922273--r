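#' Simulate endotype-conditional clinical variables
#'
#' Fills the clinical columns of the sample metadata. For idiopathic
#' patients the CSF assays and clinical scores are drawn from
#' endotype-conditional distributions: p-tau (pg/mL, log-normal) straddles
#' the 11 pg/mL boundary (endotype 1 above, endotype 2 below), and amyloid
#' beta, total tau and alpha-synuclein are lower while UPDRS part I is
#' higher in endotype 2; MoCA carries no endotype shift. Controls and
#' genetic-subcohort samples are drawn from the endotype-free reference
#' distributions.
#'
#' @param config a [sim_config()].
#' @param truth a `ground_truth` carrying the endotype labels.
#' @param meta the `sample_meta` to fill.
#' @param shift_scale multiplier on every endotype shift; 0 gives the null
#'   cohort in which no clinical variable separates the endotypes.
#' @param noise_scale multiplier on the within-endotype spreads; small
#'   values give fully separable endotypes (used for tree sanity checks).
#' @return `meta` with clinical columns ptau, abeta, ttau, asyn, updrs1,
#'   moca appended.
#' @export
simulate_clinical_cohort <- function(config, truth, meta,
                                     shift_scale = 1, noise_scale = 1) {
  stopifnot(inherits(config, "sim_config"))
  et <- truth$samples$endotype[match(meta$sample_id, truth$samples$sample_id)]
  if (all(is.na(et)))
    stop("endotype labels have not been assigned; run simulate_sample_meta()/simulate_proteome() first")
  set.seed(stage_seed(config, "clinical"))
  n <- nrow(meta)
  # signed endotype indicator: -1 endotype 1, +1 endotype 2, 0 otherwise
  s <- ifelse(is.na(et), 0, ifelse(et == 2L, 1, -1))

  # p-tau: log-normal around 11 pg/mL; endotype shifts of +/-0.24 on the log
  # scale put endotype means near 14 (e1) and 8.7 (e2)
  lshift <- 0.24 * shift_scale
  meta$ptau <- round(exp(stats::rnorm(n, log(11) - s * lshift,
                                      0.25 * noise_scale)), 2)
  meta$abeta <- round(stats::rnorm(n, 850 - s * 100 * shift_scale,
                                   180 * noise_scale), 1)
  meta$ttau <- round(stats::rnorm(n, 170 - s * 25 * shift_scale,
                                  45 * noise_scale), 1)
  meta$asyn <- round(stats::rnorm(n, 1450 - s * 160 * shift_scale,
                                  340 * noise_scale), 1)
  meta$updrs1 <- pmax(0, round(stats::rnorm(n, 5.5 + s * 0.8 * shift_scale,
                                            2.6 * noise_scale)))
  meta$moca <- pmin(30, round(stats::rnorm(n, 27, 2 * noise_scale)))
  meta
}

#' Simulate a complete synthetic cohort
#'
#' One-call wrapper running [simulate_genotypes()], [simulate_sample_meta()],
#' [simulate_proteome()], [simulate_gwas_summary()] and
#' [simulate_clinical_cohort()] under a single configuration. All output is
#' fully determined by `config$seed`.
#'
#' @param config a [sim_config()].
#' @param scenario colocalization scenario passed to
#'   [simulate_gwas_summary()].
#' @param swap_frac passed to [simulate_gwas_summary()].
#' @return list of class `sim_cohort`: `config`, `genotypes`, `meta`
#'   (clinical columns filled), `proteome`, `truth`, `gwas`.
#' @export
simulate_cohort <- function(config = sim_config(), scenario = "shared",
                            swap_frac = 0) {
  genotypes <- simulate_genotypes(config)
  meta <- simulate_sample_meta(config)
  sp <- simulate_proteome(config, genotypes, meta)
  gwas <- simulate_gwas_summary(config, sp$truth, genotypes,
                                scenario = scenario, swap_frac = swap_frac)
  meta <- simulate_clinical_cohort(config, sp$truth, meta)
  structure(list(config = config, genotypes = genotypes, meta = meta,
                 proteome = sp$proteome, truth = sp$truth, gwas = gwas),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("Synthetic proteogenomic cohort\n")
  print(x$genotypes)
  print(x$proteome)
  ta <- x$truth$analytes
  cat(sprintf("  %d cis-regulated analytes, %d causal (theta=%.2f)\n",
              sum(ta$is_regulated), sum(ta$causal), x$config$theta_causal))
  cat(sprintf("  subcohorts: %s\n",
              paste(names(table(x$meta$subcohort)),
                    table(x$meta$subcohort), sep = "=", collapse = ", ")))
  invisible(x)
}

#' Write all cohort tables as TSV files
#' @param cohort a `sim_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort_tsv <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_genotype_tsv(cohort$genotypes, file.path(dir, "genotypes.tsv"))
  write_proteome_tsv(cohort$proteome, file.path(dir, "proteome.tsv"))
  utils::write.table(cohort$meta, file.path(dir, "samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_gwas_tsv(cohort$gwas, file.path(dir, "gwas.tsv"))
  utils::write.table(cohort$truth$analytes, file.path(dir, "truth_analytes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$truth$samples, file.path(dir, "truth_samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
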