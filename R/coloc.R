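#' Colocalization configuration
#'
#' Prior probabilities of the five-hypothesis colocalization model and the
#' prior effect scales of the two traits. The probability defaults are the
#' standard single-causal-variant priors (`p1 = p2 = 1e-4`, `p12 = 1e-5`);
#' the effect-sd defaults follow the convention of a quantitative molecular
#' trait (0.15) against a case-control outcome on the log-odds scale (0.2).
#'
#' @param p1 prior probability a variant is associated with trait 1 (pQTL).
#' @param p2 prior probability a variant is associated with trait 2 (GWAS).
#' @param p12 prior probability a variant is associated with both.
#' @param sd1 prior effect sd of trait 1 (quantitative; 0.15).
#' @param sd2 prior effect sd of trait 2 (case-control log-odds; 0.2).
#' @param pph4_strong threshold for the strong-colocalization flag (0.75).
#' @return an object of class `coloc_config`.
#' @export
coloc_config <- function(p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                         sd1 = 0.15, sd2 = 0.2, pph4_strong = 0.75) {
  if (p1 + p2 + p12 >= 1) stop("p1 + p2 + p12 must be < 1")
  if (sd1 <= 0 || sd2 <= 0) stop("prior effect sds must be positive")
  structure(list(p1 = p1, p2 = p2, p12 = p12, sd1 = sd1, sd2 = sd2,
                 pph4_strong = pph4_strong), class = "coloc_config")
}

#' Wakefield approximate Bayes factor (log scale)
#'
#' For a variant with estimated effect `beta`, standard error `se` and a
#' normal effect prior of scale `prior_sd`: with `V = se^2`, `W =
#' prior_sd^2` and `z = beta/se`, the approximate Bayes factor against the
#' null is `log ABF = 0.5 log(V/(V+W)) + W z^2 / (2 (V+W))`, i.e. the
#' ratio of the two normal marginal likelihoods. Returned in log space for
#' numerical stability at large z.
#'
#' @param beta effect estimate(s).
#' @param se standard error(s), positive.
#' @param prior_sd prior effect scale.
#' @return log approximate Bayes factor(s), vectorized.
#' @export
wakefield_abf <- function(beta, se, prior_sd) {
  if (any(se <= 0)) stop("standard errors must be positive")
  V <- se^2
  W <- prior_sd^2
  z <- beta / se
  0.5 * log(V / (V + W)) + W * z^2 / (2 * (V + W))
}

#' Five-hypothesis colocalization posteriors for one region
#'
#' Single-causal-variant colocalization of two association signals over a
#' shared variant set. Per-variant log ABFs are combined into the
#' unnormalized hypothesis weights `L0 = 1`, `L1 = p1 sum(BF1)`,
#' `L2 = p2 sum(BF2)`, `L3 = p1 p2 (sum(BF1) sum(BF2) - sum(BF1*BF2))`,
#' `L4 = p12 sum(BF1*BF2)`, all in log space with log-sum-exp; posteriors
#' are `PPHk = Lk / sum(L)`. H4 is the shared-causal-variant hypothesis;
#' `PPH4 > pph4_strong` is flagged as strong colocalization.
#'
#' @param pqtl_region data.frame with variant_id, beta, se for the pQTL
#'   trait over the region.
#' @param gwas_region data.frame with variant_id, beta, se for the outcome.
#' @param config a [coloc_config()].
#' @return object of class `coloc_result`: region posteriors PPH0-PPH4,
#'   n_snps, strong flag.
#' @export
coloc_posteriors <- function(pqtl_region, gwas_region, config = coloc_config()) {
  shared <- intersect(pqtl_region$variant_id, gwas_region$variant_id)
  if (!length(shared)) stop("no shared variants between the two regions")
  i1 <- match(shared, pqtl_region$variant_id)
  i2 <- match(shared, gwas_region$variant_id)
  l1 <- wakefield_abf(pqtl_region$beta[i1], pqtl_region$se[i1], config$sd1)
  l2 <- wakefield_abf(gwas_region$beta[i2], gwas_region$se[i2], config$sd2)

  ls1 <- logsumexp(l1)
  ls2 <- logsumexp(l2)
  ls12 <- logsumexp(l1 + l2)
  L0 <- 0
  L1 <- log(config$p1) + ls1
  L2 <- log(config$p2) + ls2
  L4 <- log(config$p12) + ls12
  # L3: cross-product sum minus the diagonal, in log space
  gap <- ls12 - (ls1 + ls2)
  if (length(shared) == 1L || gap >= 0) {
    if (gap > 1e-9 && length(shared) > 1L)
      warning("negative L3 from round-off; clamped at 0")
    L3 <- -Inf
  } else {
    L3 <- log(config$p1) + log(config$p2) + ls1 + ls2 + log1p(-exp(gap))
  }
  L <- c(L0, L1, L2, L3, L4)
  pp <- exp(L - logsumexp(L))
  names(pp) <- paste0("PPH", 0:4)
  structure(list(pp = pp, n_snps = length(shared),
                 strong = unname(pp["PPH4"] > config$pph4_strong),
                 config = config), class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("coloc over %d variants: %s%s\n", x$n_snps,
              paste(names(x$pp), sprintf("%.3f", x$pp), sep = "=", collapse = " "),
              if (x$strong) "  [strong colocalization]" else ""))
  invisible(x)
}

#' Colocalize every protein's cis region against the outcome GWAS
#'
#' Runs [coloc_posteriors()] on the cis window of each analyte, using the
#' pQTL scan records as trait 1 and the GWAS summary as trait 2.
#'
#' @param pqtls a `pqtl_scan` table.
#' @param gwas a `gwas_summary`.
#' @param config a [coloc_config()].
#' @return data.frame: analyte_id, n_snps, PPH0-PPH4, strong.
#' @export
coloc_regions <- function(pqtls, gwas, config = coloc_config()) {
  res <- lapply(split(as.data.frame(pqtls), pqtls$analyte_id), function(reg) {
    cr <- coloc_posteriors(reg[, c("variant_id", "beta", "se")],
                           gwas[, c("variant_id", "beta", "se")], config)
    data.frame(analyte_id = reg$analyte_id[1L], n_snps = cr$n_snps,
               as.list(cr$pp), strong = cr$strong,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
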