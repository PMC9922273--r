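#' Map analytes to their cis windows
#'
#' A variant is cis to an analyte when it lies on the same chromosome within
#' the +/-1 Mb region flanking the encoding gene, boundary positions
#' included; window starts are clamped at position 1. Analytes without gene
#' coordinates are excluded with a warning and listed in the `excluded`
#' attribute. For analytes whose aptamer targets several genes, pass one row
#' per gene with the same `analyte_id`: the windows are unioned.
#'
#' @param analytes data.frame with analyte_id, chrom, gene_start, gene_end
#'   (1-based, inclusive).
#' @param variants data.frame with variant_id, chrom, pos (1-based).
#' @param flank window half-width in bp; 1e6 by default.
#' @return named list: per analyte, the character vector of cis variant ids.
#' @export
map_cis_windows <- function(analytes, variants, flank = 1e6) {
  ok <- !is.na(analytes$chrom) & !is.na(analytes$gene_start) &
    !is.na(analytes$gene_end)
  if (any(!ok))
    warning("excluding ", sum(!ok), " analyte(s) with missing gene coordinates: ",
            paste(utils::head(analytes$analyte_id[!ok], 5L), collapse = ", "))
  windows <- lapply(split(analytes[ok, , drop = FALSE],
                          analytes$analyte_id[ok]), function(aa) {
    hits <- character(0)
    for (i in seq_len(nrow(aa))) {
      lo <- max(1, aa$gene_start[i] - flank)
      hi <- aa$gene_end[i] + flank
      hits <- c(hits, variants$variant_id[variants$chrom == aa$chrom[i] &
                                            variants$pos >= lo &
                                            variants$pos <= hi])
    }
    unique(hits)
  })
  # preserve input analyte order
  windows <- windows[intersect(unique(analytes$analyte_id[ok]), names(windows))]
  attr(windows, "excluded") <- analytes$analyte_id[!ok]
  windows
}

#' Covariate-adjusted cis-pQTL scan
#'
#' Regresses each (inverse-normal-transformed) analyte on the dosage of each
#' of its cis variants, adjusted for covariates. Implemented by
#' residualizing both analytes and dosages on the covariate design once
#' (Frisch-Waugh) with residual degrees of freedom `n - rank(design) - 1`,
#' which reproduces per-pair OLS exactly while scanning all pairs in one
#' pass. Variants with MAF at or below `maf_min` are excluded before
#' testing; variants monomorphic in the sample are skipped and listed in
#' the `skipped` attribute.
#'
#' @param proteins samples x analytes matrix (typically INT-transformed).
#' @param genotypes a `genotype_matrix` (or list with `dosage`, `variants`).
#' @param covariates data.frame or model matrix of covariates (age, sex,
#'   subcohort, protein PCs 1-4, genetic PCs 1-10 in the standard design);
#'   `NULL` for intercept only.
#' @param windows mapping from [map_cis_windows()].
#' @param maf_min minor-allele-frequency filter (strict `>`); default 0.05.
#' @return data.frame of class `pqtl_scan`: analyte_id, variant_id, beta,
#'   se, t, p, n.
#' @export
scan_pqtl <- function(proteins, genotypes, covariates = NULL, windows,
                      maf_min = 0.05) {
  check_matrix(proteins, "proteins")
  dosage <- genotypes$dosage
  if (!identical(rownames(proteins), rownames(dosage)))
    stop("proteins and genotypes must cover the same samples in the same order")
  n <- nrow(proteins)
  X <- if (is.null(covariates)) matrix(1, n, 1L)
  else cbind(1, if (is.matrix(covariates)) covariates
             else stats::model.matrix(~ ., data = as.data.frame(covariates))[, -1, drop = FALSE])
  qx <- qr(X)
  if (qx$rank < ncol(X)) stop("covariate design is rank deficient")
  df <- n - qx$rank - 1L
  if (df < 1L) stop("not enough samples for the covariate design")

  maf <- pmin(colMeans(dosage) / 2, 1 - colMeans(dosage) / 2)
  keep <- names(which(maf > maf_min))

  ry <- qr.resid(qx, proteins)
  rg <- qr.resid(qx, dosage[, keep, drop = FALSE])
  gg <- colSums(rg^2)
  mono <- gg < 1e-12
  skipped <- keep[mono]

  res <- vector("list", length(windows))
  for (i in seq_along(windows)) {
    aid <- names(windows)[i]
    vs <- intersect(windows[[i]], keep[!mono])
    if (!length(vs)) next
    y <- ry[, aid]
    g <- rg[, vs, drop = FALSE]
    gy <- crossprod(g, y)[, 1L]
    beta <- gy / gg[vs]
    rss <- sum(y^2) - beta * gy
    se <- sqrt(rss / df / gg[vs])
    tt <- beta / se
    res[[i]] <- data.frame(analyte_id = aid, variant_id = vs,
                           beta = beta, se = se, t = tt,
                           p = 2 * stats::pt(-abs(tt), df), n = n,
                           stringsAsFactors = FALSE, row.names = NULL)
  }
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(analyte_id = character(0), variant_id = character(0),
                      beta = numeric(0), se = numeric(0), t = numeric(0),
                      p = numeric(0), n = integer(0))
  attr(out, "df") <- df
  attr(out, "skipped") <- skipped
  class(out) <- c("pqtl_scan", "data.frame")
  out
}

#' Significant cis-pQTLs and per-analyte lead variants
#'
#' Applies the genome-wide threshold with a strict inequality
#' (`p < alpha`); a record at exactly `alpha` is excluded.
#'
#' @param records a `pqtl_scan` table.
#' @param alpha significance threshold; genome-wide 5e-8 by default.
#' @return list of class `cis_pqtl_hits`: `significant` (all passing
#'   records) and `lead` (the best record per analyte, among all tested).
#' @export
significant_cis_pqtls <- function(records, alpha = 5e-8) {
  sig <- records[!is.na(records$p) & records$p < alpha, , drop = FALSE]
  lead <- do.call(rbind, lapply(split(seq_len(nrow(records)),
                                      records$analyte_id), function(ix) {
    records[ix[which.min(records$p[ix])], , drop = FALSE]
  }))
  rownames(sig) <- rownames(lead) <- NULL
  structure(list(significant = sig, lead = lead, alpha = alpha),
            class = "cis_pqtl_hits")
}

#' @export
print.cis_pqtl_hits <- function(x, ...) {
  cat(sprintf("cis-pQTL hits at p < %g: %d records over %d analyte(s)\n",
              x$alpha, nrow(x$significant),
              length(unique(x$significant$analyte_id))))
  invisible(x)
}

#' Write a pQTL scan as TSV
#' @param records a `pqtl_scan` table.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pqtl_tsv <- function(records, path) {
  utils::write.table(as.data.frame(records), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
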