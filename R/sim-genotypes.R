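#' Simulate LD-blocked biallelic genotype dosages
#'
#' Genotypes are generated with a Gaussian copula: within each LD block a
#' latent AR(1) Gaussian process (correlation `ld_rho` between neighbours)
#' is drawn independently for each of two haplotypes per individual and
#' thresholded at the allele-frequency quantile, so allele frequencies match
#' the target MAF, genotypes are in Hardy-Weinberg proportions, and dosage
#' correlation decays within blocks and vanishes across blocks. Variants are
#' laid on one synthetic chromosome at uniform spacing so that +/-1 Mb cis
#' windows hold a predictable number of variants.
#'
#' @param config a [sim_config()].
#' @return an object of class `genotype_matrix`: a list with `dosage`
#'   (samples x variants integer matrix, entries 0/1/2) and `variants`
#'   (data.frame: variant_id, chrom, pos, ref, alt, eaf, maf, block).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config, "genotypes"))
  n <- config$n_samples
  m <- config$n_variants
  bs <- config$ld_block_size
  rho <- config$ld_rho
  maf <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  thr <- stats::qnorm(maf)

  # latent AR(1) per block, one column of innovations at a time
  draw_haplotype <- function() {
    z <- matrix(stats::rnorm(n * m), n, m)
    for (b in seq_len(m / bs)) {
      cols <- ((b - 1) * bs + 1):(b * bs)
      for (j in cols[-1]) z[, j] <- rho * z[, j - 1] + sqrt(1 - rho^2) * z[, j]
    }
    z
  }
  h1 <- sweep(draw_haplotype(), 2, thr, "<")
  h2 <- sweep(draw_haplotype(), 2, thr, "<")
  dosage <- h1 + h2
  storage.mode(dosage) <- "integer"

  # allele labels: sampled pairs; palindromic (A/T, C/G) pairs arise naturally
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, m, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")
  variants <- data.frame(
    variant_id = sprintf("var%04d", seq_len(m)),
    chrom = "1",
    pos = as.integer(seq_len(m) * config$variant_spacing),
    ref = ref, alt = unname(alt),
    eaf = colMeans(dosage) / 2,
    maf = maf,
    block = rep(seq_len(m / bs), each = bs),
    stringsAsFactors = FALSE)
  rownames(dosage) <- sprintf("S%04d", seq_len(n))
  colnames(dosage) <- variants$variant_id
  structure(list(dosage = dosage, variants = variants),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d variants (%d LD blocks)\n",
              nrow(x$dosage), ncol(x$dosage), max(x$variants$block)))
  invisible(x)
}

#' Write genotype dosages as a minimal VCF
#'
#' Emits a sites-by-samples VCF 4.2 with a single `DS` FORMAT field carrying
#' the dosage (no GT), which is sufficient for dosage-based downstream tools.
#'
#' @param genotypes a `genotype_matrix`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_genotype_vcf <- function(genotypes, path) {
  v <- genotypes$variants
  d <- genotypes$dosage
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage of ALT allele\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(d)), collapse = "\t")), con)
  body <- apply(cbind(v$chrom, v$pos, v$variant_id, v$ref, v$alt, ".", "PASS",
                      paste0("AF=", signif(v$eaf, 6)), "DS",
                      t(d)), 1L, paste, collapse = "\t")
  writeLines(body, con)
  invisible(path)
}

#' Write genotype dosages as TSV
#' @param genotypes a `genotype_matrix`.
#' @param path output file path for the dosage table; variant metadata goes
#'   to `sub("\\.tsv$", "_variants.tsv", path)`.
#' @return `path`, invisibly.
#' @export
write_genotype_tsv <- function(genotypes, path) {
  d <- data.frame(sample_id = rownames(genotypes$dosage),
                  genotypes$dosage, check.names = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(genotypes$variants, sub("\\.tsv$", "_variants.tsv", path),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
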