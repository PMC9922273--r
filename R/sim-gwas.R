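#' Simulate external GWAS summary statistics with protein-mediated effects
#'
#' Emulates a large external case-control GWAS of the disease trait without
#' simulating individuals: in a virtual cohort the trait is
#' `y = sum_c theta_c * (beta_c * x_vc) + direct pleiotropic effects + noise`,
#' and the marginal per-variant regression slope is computed analytically
#' from the dosage covariances of the supplied genotype panel (exact zero
#' across independent LD blocks), then perturbed with sampling noise at the
#' configured GWAS sample size. Under `scenario = "distinct"` each causal
#' protein's trait signal is moved to a variant in a different LD block of
#' the same cis region (low LD with the protein's cis variant), the
#' colocalization null of two distinct causal variants.
#'
#' @param config a [sim_config()].
#' @param truth a `ground_truth` from [simulate_proteome()].
#' @param genotypes the `genotype_matrix` used as LD/frequency panel.
#' @param scenario `"shared"` (trait acts through the protein's cis variant)
#'   or `"distinct"` (trait signal at a separate variant in low LD).
#' @param swap_frac fraction of records emitted with effect/other alleles
#'   swapped (beta sign flipped, EAF complemented) and flagged in the
#'   `swapped` column, to exercise harmonization.
#' @return data.frame of class `gwas_summary` with columns variant_id,
#'   chrom, pos, effect_allele, other_allele, eaf, beta, se, pval, n,
#'   swapped, plus the per-variant true marginal slope in `beta_true`.
#' @export
simulate_gwas_summary <- function(config, truth, genotypes,
                                  scenario = c("shared", "distinct"),
                                  swap_frac = 0) {
  stopifnot(inherits(config, "sim_config"))
  scenario <- match.arg(scenario)
  set.seed(stage_seed(config, "gwas"))
  v <- genotypes$variants
  d <- genotypes$dosage
  m <- nrow(v)

  ta <- truth$analytes
  causal <- ta[ta$causal, , drop = FALSE]
  # direct genetic effects on the trait, keyed by variant index
  alpha <- numeric(m)
  if (nrow(causal)) {
    for (i in seq_len(nrow(causal))) {
      ci <- match(causal$cis_variant[i], v$variant_id)
      if (scenario == "shared") {
        # mediated: theta * beta_cis at the protein's cis variant
        alpha[ci] <- alpha[ci] + causal$theta[i] * causal$cis_beta[i]
      } else {
        # distinct causal variant: same region, different LD block
        reg <- which(v$block != v$block[ci] &
                       abs(v$pos - v$pos[ci]) <= 1e6)
        if (!length(reg)) reg <- setdiff(seq_len(m), ci)
        w <- reg[sample.int(length(reg), 1L)]
        alpha[w] <- alpha[w] + causal$theta[i] * causal$cis_beta[i]
      }
    }
    if (config$pleiotropy_frac > 0) {
      # direct effects at instruments: cis variants of causal proteins' regions
      for (i in seq_len(nrow(causal))) {
        ci <- match(causal$cis_variant[i], v$variant_id)
        reg <- which(v$chrom == v$chrom[ci] & abs(v$pos - v$pos[ci]) <= 1e6)
        hit <- reg[stats::runif(length(reg)) < config$pleiotropy_frac]
        alpha[hit] <- alpha[hit] + stats::rnorm(length(hit), 0, config$pleiotropy_sd)
      }
    }
  }

  # analytic marginal slopes: b_j = sum_k alpha_k cov(x_j, x_k) / var(x_j),
  # with cross-block covariance exactly zero by construction
  covd <- function(j, k) if (v$block[j] != v$block[k]) 0 else stats::cov(d[, j], d[, k])
  varx <- apply(d, 2, stats::var)
  beta_true <- numeric(m)
  hot <- which(alpha != 0)
  for (k in hot) {
    blk <- which(v$block == v$block[k])
    for (j in blk) beta_true[j] <- beta_true[j] + alpha[k] * covd(j, k) / varx[j]
  }

# trait variance: unit noise plus the genetic quadratic form (same-block pairs)
  var_y <- 1 + sum(vapply(hot, function(k) {
    blk <- hot[v$block[hot] == v$block[k]]
    sum(vapply(blk, function(l) alpha[k] * alpha[l] * covd(k, l), 0))
  }, 0))
  se <- sqrt(pmax(var_y - beta_true^2 * varx, 0.25)) / sqrt(varx * config$gwas_n)
  beta_hat <- beta_true + stats::rnorm(m, 0, se)
  z <- beta_hat / se
  pval <- 2 * stats::pnorm(-abs(z))
  eaf <- stats::rbinom(m, size = round(2 * config$gwas_n), prob = v$eaf) /
    round(2 * config$gwas_n)

  out <- data.frame(variant_id = v$variant_id, chrom = v$chrom, pos = v$pos,
                    effect_allele = v$alt, other_allele = v$ref,
                    eaf = eaf, beta = beta_hat, se = se, pval = pval,
                    n = round(config$gwas_n), swapped = FALSE,
                    beta_true = beta_true,
                    stringsAsFactors = FALSE)
  if (swap_frac > 0) {
    sw <- stats::runif(m) < swap_frac
    out$effect_allele[sw] <- v$ref[sw]
    out$other_allele[sw] <- v$alt[sw]
    out$beta[sw] <- -out$beta[sw]
    out$beta_true[sw] <- -out$beta_true[sw]
    out$eaf[sw] <- 1 - out$eaf[sw]
    out$swapped <- sw
  }
  class(out) <- c("gwas_summary", "data.frame")
  out
}

#' Write GWAS summary statistics as TSV
#' @param gwas a `gwas_summary` data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gwas_tsv <- function(gwas, path) {
  cols <- c("variant_id", "chrom", "pos", "effect_allele", "other_allele",
            "eaf", "beta", "se", "pval", "n")
  utils::write.table(gwas[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read GWAS summary statistics from TSV
#' @param path TSV with header variant_id, chrom, pos, effect_allele,
#'   other_allele, eaf, beta, se, pval, n.
#' @return a `gwas_summary` data.frame.
#' @export
read_gwas_tsv <- function(path) {
  g <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("variant_id", "chrom", "pos", "effect_allele", "other_allele",
            "eaf", "beta", "se", "pval", "n")
  miss <- setdiff(need, names(g))
  if (length(miss)) stop("GWAS table lacks columns: ", paste(miss, collapse = ", "))
  g$chrom <- as.character(g$chrom)
  class(g) <- c("gwas_summary", "data.frame")
  g
}
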