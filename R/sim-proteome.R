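#' Simulate cohort sample metadata
#'
#' Draws demographic and design covariates for the cohort: age, sex, study
#' centre, assay plate, the three subcohorts (idiopathic / GBA+ / LRRK2+)
#' with their case/control status, a medication flag (genetic-subcohort
#' patients only; idiopathic patients are drug-naive), and the latent
#' endotype label of idiopathic patients which downstream clinical and
#' proteomic structure is conditioned on.
#'
#' @param config a [sim_config()].
#' @return data.frame of class `sample_meta` with one row per sample:
#'   sample_id, age, sex, center, plate, subcohort (none/GBA/LRRK2),
#'   status (case/control), treated, endotype (1/2 for idiopathic cases,
#'   NA otherwise).
#' @export
simulate_sample_meta <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config, "meta"))
  n <- config$n_samples
  p <- config$subcohort_props
  cell <- sample(names(p), n, replace = TRUE, prob = p)
  subcohort <- c(ipd = "none", hc = "none", gba_pd = "GBA", gba_uc = "GBA",
                 lrrk2_pd = "LRRK2", lrrk2_uc = "LRRK2")[cell]
  status <- ifelse(cell %in% c("ipd", "gba_pd", "lrrk2_pd"), "case", "control")
  treated <- status == "case" & subcohort != "none" &
    stats::runif(n) < config$treated_frac
  meta <- data.frame(
    sample_id = sprintf("S%04d", seq_len(n)),
    age = round(stats::rnorm(n, 61, 10), 1),
    sex = sample(c("M", "F"), n, replace = TRUE),
    center = sample(sprintf("C%02d", seq_len(config$n_centers)), n, replace = TRUE),
    plate = sample(sprintf("P%02d", seq_len(config$n_plates)), n, replace = TRUE),
    subcohort = subcohort, status = status, treated = treated,
    endotype = NA_integer_,
    stringsAsFactors = FALSE)
  idio <- which(meta$subcohort == "none" & meta$status == "case")
  n2 <- round(config$endotype_frac * length(idio))
  e2 <- sample(idio, n2)
  meta$endotype[idio] <- 1L
  meta$endotype[e2] <- 2L
  rownames(meta) <- meta$sample_id
  class(meta) <- c("sample_meta", "data.frame")
  meta
}

#' Simulate the log2-scale proteome with known ground truth
#'
#' Each analyte is a sum of an analyte baseline, age/sex/centre covariate
#' effects, a cis dosage effect for regulated analytes, optional
#' case-control disease effects, module latent-factor structure (two
#' planted co-expression modules whose factors shift between the two
#' idiopathic endotypes), plate location/scale batch effects, and Gaussian
#' noise, all on log2 scale. Every injected effect is recorded in the
#' returned ground truth so independent oracles can recover it.
#'
#' @param config a [sim_config()].
#' @param genotypes a `genotype_matrix` from [simulate_genotypes()].
#' @param meta a `sample_meta` from [simulate_sample_meta()].
#' @return list of class `sim_proteome` with elements
#'   `proteome` (class `protein_matrix`: `values` samples x analytes,
#'   `analytes` metadata with gene coordinates and dilution group) and
#'   `truth` (class `ground_truth`: per-analyte cis variant/beta, causal
#'   flag and theta, module and disease effects; per-sample endotype;
#'   per-plate batch parameters).
#' @export
simulate_proteome <- function(config, genotypes, meta) {
  stopifnot(inherits(config, "sim_config"))
  if (!identical(rownames(genotypes$dosage), meta$sample_id))
    stop("genotypes and sample metadata refer to different sample sets")
  set.seed(stage_seed(config, "proteome"))
  n <- config$n_samples
  a <- config$n_analytes
  v <- genotypes$variants

  # gene placement: analytes spread uniformly along the synthetic chromosome
  span <- range(v$pos)
  centre <- round(seq(span[1], span[2], length.out = a))
  analytes <- data.frame(
    analyte_id = sprintf("apt%04d", seq_len(a)),
    gene = sprintf("GENE%04d", seq_len(a)),
    chrom = "1",
    gene_start = pmax(1L, as.integer(centre - 5000L)),
    gene_end = as.integer(centre + 5000L),
    dilution = sample(c("20%", "0.5%", "0.005%"), a, replace = TRUE,
                      prob = c(0.7, 0.2, 0.1)),
    stringsAsFactors = FALSE)

  # cis regulation: regulated analytes get one causal variant in their window
  regulated <- sort(sample(a, round(config$prop_cis_regulated * a)))
  cis_variant <- rep(NA_character_, a)
  cis_beta <- rep(0, a)
  for (i in regulated) {
    w <- which(v$chrom == analytes$chrom[i] &
                 v$pos >= analytes$gene_start[i] - 1e6 &
                 v$pos <= analytes$gene_end[i] + 1e6)
    cis_variant[i] <- v$variant_id[w[sample.int(length(w), 1L)]]
    cis_beta[i] <- if (config$cis_effect_dist == "fixed")
      sample(c(-1, 1), 1L) * config$cis_effect_sd
    else stats::rnorm(1L, 0, config$cis_effect_sd)
  }

  # causal proteins: subset of regulated analytes affecting the GWAS trait
  causal <- logical(a)
  if (length(regulated)) {
    k <- round(config$causal_frac * length(regulated))
    causal[regulated[sample.int(length(regulated), k)]] <- TRUE
  }
  theta <- ifelse(causal, config$theta_causal, 0)

  # planted co-expression modules with endotype-shifted latent factors
  module <- integer(a)
  sizes <- round(config$module_sizes * a)
  sizes <- pmax(2L, sizes)[sizes > 0]
  free <- setdiff(seq_len(a), integer(0))
  for (mdl in seq_along(sizes)) {
    pick <- sample(free, sizes[mdl])
    module[pick] <- mdl
    free <- setdiff(free, pick)
  }
  loading <- stats::runif(a, config$module_loading_range[1],
                          config$module_loading_range[2]) * (module > 0)
  esign <- ifelse(is.na(meta$endotype), 0, ifelse(meta$endotype == 2L, 1, -1))
  factors <- sapply(seq_along(sizes), function(mdl)
    stats::rnorm(n) + esign * config$endotype_sep / 2)

  # disease effects for DE testing (none by default)
  de_effect <- rep(0, a)
  if (config$disease_frac > 0) {
    de_idx <- sample(a, round(config$disease_frac * a))
    de_effect[de_idx] <- config$disease_effect * sample(c(-1, 1), length(de_idx), TRUE)
  }

  # covariate effects
  beta_age <- stats::rnorm(a, 0, 0.004)
  beta_sex <- stats::rnorm(a, 0, 0.05)
  centers <- sort(unique(meta$center))
  beta_center <- matrix(stats::rnorm(length(centers) * a, 0, 0.05),
                        length(centers), a, dimnames = list(centers, NULL))

  base <- stats::rnorm(a, 10, 1.5)
  agec <- meta$age - mean(meta$age)
  sexm <- as.numeric(meta$sex == "M")
  case <- as.numeric(meta$status == "case")

  clean <- matrix(base, n, a, byrow = TRUE) +
    outer(agec, beta_age) +
    outer(sexm, beta_sex) +
    beta_center[meta$center, , drop = FALSE] +
    outer(case, de_effect)
  for (mdl in seq_along(sizes)) {
    in_m <- module == mdl
    clean[, in_m] <- clean[, in_m] +
      outer(factors[, mdl], loading[in_m])
  }
  reg_cols <- which(!is.na(cis_variant))
  if (length(reg_cols))
    clean[, reg_cols] <- clean[, reg_cols] +
      genotypes$dosage[, cis_variant[reg_cols], drop = FALSE] %*%
      diag(cis_beta[reg_cols], nrow = length(reg_cols))

  # plate batch effects: additive location + multiplicative noise scale
  plates <- sort(unique(meta$plate))
  gamma <- matrix(stats::rnorm(length(plates) * a, 0, config$plate_shift_sd),
                  length(plates), a, dimnames = list(plates, NULL))
  delta <- matrix(exp(stats::rnorm(length(plates) * a, 0, config$plate_scale_sd)),
                  length(plates), a, dimnames = list(plates, NULL))
  # heteroskedastic residuals: lognormal per-analyte sds with mean variance
  # noise_sd^2 (the -s^2 term recentres the lognormal second moment)
  s2 <- config$noise_logsd^2
  sigma_a <- config$noise_sd * exp(stats::rnorm(a, -s2, config$noise_logsd))
  eps <- matrix(stats::rnorm(n * a), n, a) %*% diag(sigma_a, a)
  values <- clean + gamma[meta$plate, , drop = FALSE] +
    delta[meta$plate, , drop = FALSE] * eps
  dimnames(values) <- list(meta$sample_id, analytes$analyte_id)

  proteome <- structure(list(values = values, analytes = analytes),
                        class = "protein_matrix")
  truth <- structure(list(
    analytes = data.frame(analytes[, c("analyte_id", "gene")],
                          is_regulated = !is.na(cis_variant),
                          cis_variant = cis_variant, cis_beta = cis_beta,
                          causal = causal, theta = theta,
                          module = module, loading = loading,
                          de_effect = de_effect,
                          stringsAsFactors = FALSE),
    samples = data.frame(sample_id = meta$sample_id,
                         endotype = meta$endotype,
                         stringsAsFactors = FALSE),
    plate_shift = gamma, plate_scale = delta,
    noise_sd = sigma_a), class = "ground_truth")
  # invariant: every causal analyte has a cis variant
  stopifnot(all(!causal | !is.na(cis_variant)))
  structure(list(proteome = proteome, truth = truth), class = "sim_proteome")
}

#' @export
print.protein_matrix <- function(x, ...) {
  cat(sprintf("protein_matrix: %d samples x %d analytes (log2 scale)\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Write a proteome and its analyte metadata as TSV
#' @param proteome a `protein_matrix`.
#' @param path output path for the abundance table; analyte metadata goes to
#'   `sub("\\.tsv$", "_analytes.tsv", path)`.
#' @return `path`, invisibly.
#' @export
write_proteome_tsv <- function(proteome, path) {
  d <- data.frame(sample_id = rownames(proteome$values),
                  proteome$values, check.names = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(proteome$analytes, sub("\\.tsv$", "_analytes.tsv", path),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
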