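#' Configuration for the synthetic proteogenomic cohort generator
#'
#' Collects every knob of the generator in one validated list. The defaults
#' describe the study conditions the pipeline is exercised under: a
#' multi-centre cohort with three subcohorts (idiopathic patients with
#' healthy controls plus two genetic subcohorts with matched unaffected
#' controls), LD-blocked biallelic genotypes on one synthetic chromosome, a
#' log2-scale aptamer proteome with cis genetic effects, covariate and
#' plate-batch effects, two co-expression modules carrying a latent
#' two-endotype structure among idiopathic patients, and an external GWAS
#' of the disease trait in which some proteins are causal.
#'
#' @param n_samples number of cohort samples.
#' @param n_variants number of biallelic variants (one synthetic autosome).
#' @param n_analytes number of proteomic analytes (aptamers).
#' @param ld_block_size variants per LD block; blocks are mutually independent.
#' @param ld_rho latent within-block autoregressive correlation, in `[0, 1)`.
#' @param maf_range minor-allele-frequency interval, inside `[0.05, 0.5]`
#'   (instruments require MAF > 0.05 downstream).
#' @param variant_spacing base pairs between adjacent variants; with the
#'   default 50 kb a +/-1 Mb cis window holds ~40 variants.
#' @param cis_effect_sd scale of true cis effects (log2 units per dosage).
#' @param cis_effect_dist `"normal"` draws betas from N(0, cis_effect_sd^2);
#'   `"fixed"` uses magnitude `cis_effect_sd` with random sign.
#' @param prop_cis_regulated fraction of analytes with a true cis variant.
#' @param noise_sd residual (biological + assay) sd on log2 scale; the mean
#'   residual variance across analytes is `noise_sd^2`.
#' @param noise_logsd spread of per-analyte residual sds (lognormal on the
#'   sd scale); aptamer panels are markedly heteroskedastic across analytes.
#' @param n_plates number of assay plates (batches).
#' @param plate_shift_sd sd of additive per-plate, per-analyte location shifts.
#' @param plate_scale_sd sd of log multiplicative per-plate scale factors.
#' @param n_centers number of study centres.
#' @param gwas_n virtual external GWAS sample size.
#' @param theta_causal causal effect of each causal protein on the trait.
#' @param causal_frac fraction of cis-regulated analytes that are causal.
#' @param pleiotropy_frac fraction of cis variants of causal proteins given a
#'   direct (horizontally pleiotropic) trait effect.
#' @param pleiotropy_sd sd of those direct effects.
#' @param subcohort_props named proportions for the six subcohort/status
#'   cells, mirroring the three-subcohort cohort composition.
#' @param treated_frac fraction of genetic-subcohort patients on medication
#'   (idiopathic patients are drug-naive).
#' @param endotype_frac fraction of idiopathic patients in endotype 2.
#' @param module_sizes sizes of the two planted co-expression modules as
#'   fractions of `n_analytes` (cohort-scale equivalents of the two observed
#'   modules).
#' @param module_loading_range range of factor loadings of module analytes.
#' @param endotype_sep shift of the module latent factors between endotypes,
#'   in factor sd units.
#' @param disease_frac fraction of analytes given a disease (case vs control)
#'   effect; 0 by default so the null pipeline is clean.
#' @param disease_effect log2 case-control shift for those analytes.
#' @param seed integer seed; fully determines all generator output.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_samples = 400,
                       n_variants = 300,
                       n_analytes = 150,
                       ld_block_size = 10,
                       ld_rho = 0.8,
                       maf_range = c(0.1, 0.5),
                       variant_spacing = 50000,
                       cis_effect_sd = 0.5,
                       cis_effect_dist = c("normal", "fixed"),
                       prop_cis_regulated = 0.3,
                       noise_sd = 0.4,
                       noise_logsd = 0.3,
                       n_plates = 4,
                       plate_shift_sd = 0.3,
                       plate_scale_sd = 0.1,
                       n_centers = 6,
                       gwas_n = 5e5,
                       theta_causal = 0.15,
                       causal_frac = 0.2,
                       pleiotropy_frac = 0,
                       pleiotropy_sd = 0.05,
                       subcohort_props = c(ipd = 0.32, hc = 0.17,
                                           gba_pd = 0.13, gba_uc = 0.15,
                                           lrrk2_pd = 0.12, lrrk2_uc = 0.11),
                       treated_frac = 0.7,
                       endotype_frac = 0.47,
                       module_sizes = c(0.19, 0.13),
                       module_loading_range = c(0.6, 0.9),
                       endotype_sep = 3.5,
                       disease_frac = 0,
                       disease_effect = 0.3,
                       seed = 1L) {
  cis_effect_dist <- match.arg(cis_effect_dist)
  frac_fields <- c(prop_cis_regulated = prop_cis_regulated,
                   causal_frac = causal_frac,
                   pleiotropy_frac = pleiotropy_frac,
                   treated_frac = treated_frac,
                   endotype_frac = endotype_frac,
                   disease_frac = disease_frac)
  bad <- frac_fields < 0 | frac_fields > 1
  if (any(bad))
    stop("fractions must lie in [0, 1]: ", paste(names(frac_fields)[bad], collapse = ", "))
  if (length(maf_range) != 2L || maf_range[1] > maf_range[2] ||
      maf_range[1] < 0.05 || maf_range[2] > 0.5)
    stop("maf_range must be an interval within [0.05, 0.5]")
  if (ld_rho < 0 || ld_rho >= 1) stop("ld_rho must lie in [0, 1)")
  if (n_variants %% ld_block_size != 0)
    stop("n_variants must be divisible by ld_block_size")
  if (gwas_n <= 0) stop("gwas_n must be positive")
  if (abs(sum(subcohort_props) - 1) > 1e-8)
    stop("subcohort_props must sum to 1")
  cfg <- list(n_samples = as.integer(n_samples),
              n_variants = as.integer(n_variants),
              n_analytes = as.integer(n_analytes),
              ld_block_size = as.integer(ld_block_size), ld_rho = ld_rho,
              maf_range = maf_range, variant_spacing = variant_spacing,
              cis_effect_sd = cis_effect_sd, cis_effect_dist = cis_effect_dist,
              prop_cis_regulated = prop_cis_regulated, noise_sd = noise_sd,
              noise_logsd = noise_logsd,
              n_plates = as.integer(n_plates),
              plate_shift_sd = plate_shift_sd, plate_scale_sd = plate_scale_sd,
              n_centers = as.integer(n_centers),
              gwas_n = gwas_n, theta_causal = theta_causal,
              causal_frac = causal_frac,
              pleiotropy_frac = pleiotropy_frac, pleiotropy_sd = pleiotropy_sd,
              subcohort_props = subcohort_props, treated_frac = treated_frac,
              endotype_frac = endotype_frac, module_sizes = module_sizes,
              module_loading_range = module_loading_range,
              endotype_sep = endotype_sep,
              disease_frac = disease_frac, disease_effect = disease_effect,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  %d samples, %d variants (blocks of %d, rho=%.2f), %d analytes\n",
              x$n_samples, x$n_variants, x$ld_block_size, x$ld_rho, x$n_analytes))
  cat(sprintf("  cis-regulated: %.0f%% (effect sd %.2f), causal: %.0f%% of those (theta=%.2f)\n",
              100 * x$prop_cis_regulated, x$cis_effect_sd,
              100 * x$causal_frac, x$theta_causal))
  cat(sprintf("  plates: %d (shift sd %.2f), GWAS n=%g, seed=%d\n",
              x$n_plates, x$plate_shift_sd, x$gwas_n, x$seed))
  invisible(x)
}

# derive a reproducible sub-seed for a generator stage so that stages can be
# re-run independently of each other under one master seed (kept < 2^31)
stage_seed <- function(config, stage) {
  offsets <- c(genotypes = 101L, meta = 211L, proteome = 307L,
               gwas = 401L, clinical = 503L)
  (config$seed * 7919L + offsets[[stage]]) %% .Machine$integer.max
}
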