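#' Select instrumental variables from a pQTL scan
#'
#' Keeps, per protein, the cis variants satisfying all three instrument
#' criteria: MAF > `maf_min`, F-statistic strictly larger than `f_min`
#' (with `F = (beta/se)^2`, the squared t of the pQTL regression), and
#' cis-pQTL `p < p_max`. Proteins with no surviving candidate are dropped
#' (listed in the `dropped` attribute).
#'
#' @param pqtls a `pqtl_scan` table.
#' @param variants variant metadata with variant_id, eaf, maf, effect
#'   alleles (`alt` = dosage-counted allele, `ref` = other).
#' @param maf_min,f_min,p_max the three selection thresholds
#'   (0.05, 10, 5e-8 by default).
#' @return data.frame of instrument candidates: analyte_id, variant_id,
#'   beta_exp, se_exp, p_exp, eaf_exp, effect_allele, other_allele, F.
#' @export
select_instruments <- function(pqtls, variants, maf_min = 0.05,
                               f_min = 10, p_max = 5e-8) {
  m <- match(pqtls$variant_id, variants$variant_id)
  Fstat <- (pqtls$beta / pqtls$se)^2
  keep <- variants$maf[m] > maf_min & Fstat > f_min & pqtls$p < p_max
  out <- data.frame(analyte_id = pqtls$analyte_id,
                    variant_id = pqtls$variant_id,
                    beta_exp = pqtls$beta, se_exp = pqtls$se,
                    p_exp = pqtls$p, eaf_exp = variants$eaf[m],
                    effect_allele = variants$alt[m],
                    other_allele = variants$ref[m],
                    F = Fstat, stringsAsFactors = FALSE)[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- setdiff(unique(pqtls$analyte_id), unique(out$analyte_id))
  out
}

complement_allele <- function(a) unname(c(A = "T", C = "G", G = "C", T = "A")[a])

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns the outcome GWAS to the exposure's effect allele. Records whose
#' outcome alleles are swapped relative to the exposure get their outcome
#' beta sign flipped and EAF complemented. Palindromic variants (A/T, C/G)
#' are resolved by allele frequency: kept when both EAFs are outside the
#' ambiguity band (`eaf_band`), oriented by whether the frequencies agree in
#' side; dropped otherwise. Variants matching in neither orientation, or
#' absent from the outcome, are dropped with a reason code (see the
#' `dropped` attribute).
#'
#' @param exposure instrument candidates from [select_instruments()].
#' @param outcome a `gwas_summary` data.frame.
#' @param eaf_band ambiguity band for palindromic variants; default
#'   `c(0.42, 0.58)`.
#' @return harmonized instrument table with outcome columns beta_out,
#'   se_out, eaf_out appended.
#' @export
harmonize_instruments <- function(exposure, outcome, eaf_band = c(0.42, 0.58)) {
  # re-harmonizing an aligned table is a no-op: outcome columns are rebuilt
  exposure <- exposure[setdiff(names(exposure),
                               c("beta_out", "se_out", "eaf_out"))]
  m <- match(exposure$variant_id, outcome$variant_id)
  out <- cbind(exposure,
               beta_out = outcome$beta[m], se_out = outcome$se[m],
               eaf_out = outcome$eaf[m],
               ea_out = outcome$effect_allele[m],
               oa_out = outcome$other_allele[m])
  reason <- rep(NA_character_, nrow(out))
  reason[is.na(m)] <- "absent_from_outcome"

  pal <- !is.na(out$ea_out) &
    out$effect_allele == complement_allele(out$other_allele)
  same <- !is.na(out$ea_out) & out$ea_out == out$effect_allele &
    out$oa_out == out$other_allele
  swap <- !is.na(out$ea_out) & out$ea_out == out$other_allele &
    out$oa_out == out$effect_allele

  # non-palindromic: flip swapped, drop mismatches
  flip <- swap & !pal
  reason[!pal & !same & !swap & is.na(reason)] <- "allele_mismatch"

  # palindromic: orient by EAF when both are unambiguous
  if (any(pal)) {
    clear <- function(f) !is.na(f) & (f < eaf_band[1] | f > eaf_band[2])
    side <- function(f) f > 0.5
    reason[pal & !(same | swap) & is.na(reason)] <- "allele_mismatch"
    ok <- pal & (same | swap) & clear(out$eaf_exp) & clear(out$eaf_out)
    reason[pal & (same | swap) & !ok & is.na(reason)] <- "palindromic_ambiguous"
    flip[ok & side(out$eaf_exp) != side(out$eaf_out)] <- TRUE
  }
  out$beta_out[flip] <- -out$beta_out[flip]
  out$eaf_out[flip] <- 1 - out$eaf_out[flip]

  dropped <- data.frame(variant_id = out$variant_id[!is.na(reason)],
                        reason = reason[!is.na(reason)],
                        stringsAsFactors = FALSE)
  out <- out[is.na(reason), setdiff(names(out), c("ea_out", "oa_out")),
             drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}

#' Greedy LD clumping of instruments
#'
#' Sorts instruments by exposure p-value, keeps the best, removes every
#' remaining variant whose squared Pearson dosage correlation with a kept
#' variant exceeds `r2_max`, and repeats. LD is computed from the supplied
#' genotype panel; instruments absent from the panel are dropped with a
#' warning.
#'
#' @param instruments harmonized instrument table (single protein).
#' @param genotypes a `genotype_matrix` LD panel.
#' @param r2_max LD threshold; 0.3 by default (the reported analysis
#'   setting; 0.01 gives the stringent variant).
#' @return the clumped instrument table.
#' @export
ld_clump <- function(instruments, genotypes, r2_max = 0.3) {
  if (!nrow(instruments)) return(instruments)
  present <- instruments$variant_id %in% colnames(genotypes$dosage)
  if (any(!present)) {
    warning(sum(!present), " instrument(s) absent from the LD panel; dropped")
    instruments <- instruments[present, , drop = FALSE]
  }
  if (nrow(instruments) < 2L) return(instruments)
  ord <- order(instruments$p_exp)
  cand <- ord
  kept <- integer(0)
  d <- genotypes$dosage[, instruments$variant_id, drop = FALSE]
  r2 <- stats::cor(d)^2
  while (length(cand)) {
    best <- cand[1L]
    kept <- c(kept, best)
    cand <- cand[r2[cand, best] <= r2_max]
  }
  out <- instruments[sort(kept), , drop = FALSE]
  rownames(out) <- NULL
  out
}

mr_estimate <- function(analyte_id, n_inst, method, beta, se, Q = NA_real_) {
  structure(list(analyte_id = analyte_id, n_instruments = n_inst,
                 method = method, beta = beta, se = se,
                 p = 2 * stats::pnorm(-abs(beta / se)),
                 Q = Q, pleiotropy_p = NA_real_),
            class = "mr_estimate")
}

#' Wald-ratio causal estimate from a single instrument
#'
#' `beta = beta_out / beta_exp` with first-order delta-method standard
#' error `se_out / |beta_exp|` (exposure-side variance ignored, the
#' two-sample default; set `second_order = TRUE` to add the
#' `beta_out^2 se_exp^2 / beta_exp^4` term).
#'
#' @param inst one-row instrument table.
#' @param second_order include the exposure-variance term in the SE.
#' @return an `mr_estimate`.
#' @export
mr_wald <- function(inst, second_order = FALSE) {
  if (nrow(inst) != 1L) stop("mr_wald() expects exactly one instrument")
  if (inst$beta_exp == 0) stop("undefined Wald ratio: exposure beta is zero")
  beta <- inst$beta_out / inst$beta_exp
  v <- inst$se_out^2 / inst$beta_exp^2
  if (second_order) v <- v + inst$beta_out^2 * inst$se_exp^2 / inst$beta_exp^4
  mr_estimate(inst$analyte_id, 1L, "Wald ratio", beta, sqrt(v))
}

#' Inverse-variance-weighted causal estimate
#'
#' Combines per-instrument Wald ratios with weights `1/se_j^2` (first-order
#' ratio SEs). The fixed-effect standard error `(sum w)^(-1/2)` is inflated
#' multiplicatively by `max(1, sqrt(Q/(k-1)))` (multiplicative
#' random-effects) unless `random = FALSE`; Cochran's Q is reported.
#' A single instrument is routed to [mr_wald()].
#'
#' @param insts instrument table (>= 1 row, one protein).
#' @param random apply the multiplicative random-effects inflation.
#' @param second_order passed to the ratio SE computation.
#' @return an `mr_estimate`.
#' @export
mr_ivw <- function(insts, random = TRUE, second_order = FALSE) {
  if (nrow(insts) < 2L) return(mr_wald(insts, second_order = second_order))
  r <- insts$beta_out / insts$beta_exp
  v <- insts$se_out^2 / insts$beta_exp^2
  if (second_order) v <- v + insts$beta_out^2 * insts$se_exp^2 / insts$beta_exp^4
  w <- 1 / v
  beta <- sum(w * r) / sum(w)
  Q <- sum(w * (r - beta)^2)
  se <- sqrt(1 / sum(w))
  if (random) se <- se * max(1, sqrt(Q / (nrow(insts) - 1L)))
  mr_estimate(insts$analyte_id[1L], nrow(insts), "IVW", beta, se, Q = Q)
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("MR estimate for %s (%s, %d IV%s): beta = %.4f, se = %.4f, p = %.3g\n",
              x$analyte_id, x$method, x$n_instruments,
              if (x$n_instruments > 1) "s" else "", x$beta, x$se, x$p))
  if (!is.na(x$pleiotropy_p))
    cat(sprintf("  global pleiotropy p = %.3g\n", x$pleiotropy_p))
  invisible(x)
}

#' Simulation-based global test for horizontal pleiotropy
#'
#' A global residual-sum-of-squares test in the MR-PRESSO style: the
#' observed statistic is `RSS = sum_j w_j (beta_out_j - beta_loo(-j) *
#' beta_exp_j)^2` with leave-one-out IVW predictions and weights
#' `w_j = 1/se_out_j^2`; its null distribution is obtained by parametric
#' simulation of both exposure and outcome betas from their standard errors
#' under the leave-one-out fitted model, and
#' `p = (1 + #{RSS* >= RSS_obs}) / (1 + n_sim)`. Requires at least 3
#' instruments; with fewer the p-value is undefined and `NA` is returned.
#'
#' @param insts instrument table for one protein.
#' @param n_sim number of parametric simulations (>= 100 recommended).
#' @param seed integer seed for the simulation.
#' @return the global pleiotropy p-value (`NA` when `nrow(insts) < 3`).
#' @export
presso_global_test <- function(insts, n_sim = 1000L, seed = 1L) {
  k <- nrow(insts)
  if (k < 3L) return(NA_real_)
  if (n_sim < 100L) warning("n_sim < 100 gives an unstable pleiotropy p-value")
  set.seed(seed)
  w <- 1 / insts$se_out^2
  r <- insts$beta_out / insts$beta_exp
  vr <- insts$se_out^2 / insts$beta_exp^2
  wr <- 1 / vr
  loo <- vapply(seq_len(k), function(j)
    sum(wr[-j] * r[-j]) / sum(wr[-j]), 0)
  rss_obs <- sum(w * (insts$beta_out - loo * insts$beta_exp)^2)

  be <- matrix(stats::rnorm(k * n_sim, insts$beta_exp, insts$se_exp), k)
  bo <- matrix(stats::rnorm(k * n_sim, loo * insts$beta_exp, insts$se_out), k)
  rs <- bo / be
  vrs <- insts$se_out^2 / be^2
  wrs <- 1 / vrs
  Sw <- colSums(wrs)
  Swr <- colSums(wrs * rs)
  rss_sim <- numeric(n_sim)
  for (j in seq_len(k)) {
    loo_j <- (Swr - wrs[j, ] * rs[j, ]) / (Sw - wrs[j, ])
    rss_sim <- rss_sim + w[j] * (bo[j, ] - loo_j * be[j, ])^2
  }
  (1 + sum(rss_sim >= rss_obs)) / (1 + n_sim)
}

#' Assemble the per-protein causal table with FDR
#'
#' Collects MR estimates, applies Benjamini-Hochberg FDR across proteins,
#' flags causal candidates at `fdr <= fdr_max`, and joins colocalization
#' posteriors when supplied.
#'
#' @param estimates list of `mr_estimate` objects (one per protein).
#' @param coloc optional data.frame with analyte_id and PPH0-PPH4 columns.
#' @param fdr_max candidate threshold; 0.05 by default.
#' @return data.frame of class `causal_table`: analyte_id, n_instruments,
#'   method, beta, se, p, fdr, pleiotropy_p, causal_candidate (+ coloc
#'   columns when given).
#' @export
causal_table <- function(estimates, coloc = NULL, fdr_max = 0.05) {
  tab <- do.call(rbind, lapply(estimates, function(e)
    data.frame(analyte_id = e$analyte_id, n_instruments = e$n_instruments,
               method = e$method, beta = e$beta, se = e$se, p = e$p,
               Q = e$Q, pleiotropy_p = e$pleiotropy_p,
               stringsAsFactors = FALSE)))
  tab$fdr <- bh_fdr(tab$p)
  tab$causal_candidate <- tab$fdr <= fdr_max
  if (!is.null(coloc)) tab <- merge(tab, coloc, by = "analyte_id",
                                    all.x = TRUE, sort = FALSE)
  tab <- tab[order(tab$fdr, tab$p), , drop = FALSE]
  rownames(tab) <- NULL
  class(tab) <- c("causal_table", "data.frame")
  tab
}

#' Two-sample MR across all proteins with significant cis-pQTLs
#'
#' Orchestrates instrument selection, harmonization with the outcome GWAS,
#' LD clumping, Wald-ratio/IVW estimation (Wald ratio iff exactly one
#' instrument survives clumping), the global pleiotropy test, and the
#' FDR-adjusted causal table.
#'
#' @param pqtls a `pqtl_scan` table.
#' @param gwas outcome `gwas_summary`.
#' @param genotypes LD panel for clumping.
#' @param variants variant metadata (defaults to `genotypes$variants`).
#' @param r2_max clumping threshold (0.3 default).
#' @param n_presso_sim simulations for the pleiotropy test.
#' @param seed seed for the pleiotropy simulations.
#' @param ... passed to [select_instruments()].
#' @return a `causal_table`; per-protein clumped instruments are kept in the
#'   `instruments` attribute.
#' @export
run_mr <- function(pqtls, gwas, genotypes, variants = genotypes$variants,
                   r2_max = 0.3, n_presso_sim = 1000L, seed = 1L, ...) {
  cand <- select_instruments(pqtls, variants, ...)
  harm <- harmonize_instruments(cand, gwas)
  split_h <- split(harm, harm$analyte_id)
  estimates <- list()
  instruments <- list()
  for (aid in names(split_h)) {
    insts <- ld_clump(split_h[[aid]], genotypes, r2_max = r2_max)
    if (!nrow(insts)) next
    est <- mr_ivw(insts)
    est$pleiotropy_p <- presso_global_test(insts, n_sim = n_presso_sim,
                                           seed = seed)
    estimates[[aid]] <- est
    instruments[[aid]] <- insts
  }
  if (!length(estimates)) stop("no protein retained any instrument")
  tab <- causal_table(estimates)
  attr(tab, "instruments") <- instruments
  tab
}

#' @export
print.causal_table <- function(x, ...) {
  cat(sprintf("MR causal table: %d proteins, %d causal candidate(s) at FDR <= 0.05\n",
              nrow(x), sum(x$causal_candidate)))
  print.data.frame(utils::head(as.data.frame(x), 10L), digits = 3)
  if (nrow(x) > 10L) cat("  ...\n")
  invisible(x)
}
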