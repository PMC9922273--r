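fake_variants <- function(ids, eaf = 0.3, ref = "A", alt = "C") {
  data.frame(variant_id = ids, eaf = eaf, maf = pmin(eaf, 1 - eaf),
             ref = ref, alt = alt, stringsAsFactors = FALSE)
}

fake_pqtls <- function(ids, beta, se, p, analyte = "prot1") {
  structure(data.frame(analyte_id = analyte, variant_id = ids,
                       beta = beta, se = se, t = beta / se, p = p, n = 800,
                       stringsAsFactors = FALSE),
            class = c("pqtl_scan", "data.frame"))
}

test_that("instrument selection enforces all three criteria strictly", {
  # F = (0.5/0.1)^2 = 25; weak v2 (F = 4), boundary p v3, rare v4
  pq <- fake_pqtls(c("v1", "v2", "v3", "v4"),
                   beta = c(0.5, 0.2, 0.5, 0.5),
                   se = 0.1,
                   p = c(1e-10, 1e-10, 5e-8, 1e-10))
  v <- fake_variants(c("v1", "v2", "v3", "v4"), eaf = c(0.3, 0.3, 0.3, 0.04))
  sel <- select_instruments(pq, v)
  expect_equal(sel$variant_id, "v1")   # v2: F = 4; v3: p == 5e-8; v4: MAF < 0.05
  expect_equal(sel$F, 25)
  # the F threshold itself is strict: F exactly at the cut is excluded
  sel25 <- select_instruments(fake_pqtls("v1", 0.5, 0.1, 1e-10),
                              fake_variants("v1"), f_min = 25)
  expect_equal(nrow(sel25), 0L)
  sel24 <- select_instruments(fake_pqtls("v1", 0.5, 0.1, 1e-10),
                              fake_variants("v1"), f_min = 24.9)
  expect_equal(nrow(sel24), 1L)
})

test_that("harmonization flips swapped alleles and resolves palindromes by frequency", {
  exp <- data.frame(analyte_id = "p", variant_id = c("s", "w", "pal_amb", "pal_ok", "mis"),
                    beta_exp = 0.5, se_exp = 0.1, p_exp = 1e-10,
                    eaf_exp = c(0.3, 0.3, 0.50, 0.2, 0.3),
                    effect_allele = c("A", "A", "A", "A", "A"),
                    other_allele = c("C", "C", "T", "T", "C"),
                    F = 25, stringsAsFactors = FALSE)
  out_gwas <- data.frame(variant_id = c("s", "w", "pal_amb", "pal_ok", "mis"),
                         effect_allele = c("A", "C", "A", "A", "G"),
                         other_allele = c("C", "A", "T", "T", "T"),
                         beta = 0.2, se = 0.05, eaf = c(0.3, 0.7, 0.5, 0.85, 0.3),
                         stringsAsFactors = FALSE)
  h <- harmonize_instruments(exp, out_gwas)
  expect_setequal(h$variant_id, c("s", "w", "pal_ok"))
  expect_equal(h$beta_out[h$variant_id == "s"], 0.2)      # concordant: unchanged
  expect_equal(h$beta_out[h$variant_id == "w"], -0.2)     # swapped: sign flipped
  expect_equal(h$eaf_out[h$variant_id == "w"], 0.3)
  # palindromic with discordant frequency sides: flipped
  expect_equal(h$beta_out[h$variant_id == "pal_ok"], -0.2)
  dropped <- attr(h, "dropped")
  expect_equal(dropped$reason[dropped$variant_id == "pal_amb"], "palindromic_ambiguous")
  expect_equal(dropped$reason[dropped$variant_id == "mis"], "allele_mismatch")
})

test_that("harmonizing an already-harmonized set changes nothing", {
  coh <- small_cohort()
  pq <- fake_pqtls(coh$gwas$variant_id[1:10], beta = 0.5, se = 0.1, p = 1e-10)
  v <- coh$genotypes$variants
  cand <- select_instruments(pq, v)
  h1 <- harmonize_instruments(cand, coh$gwas)
  h2 <- harmonize_instruments(h1, coh$gwas)
  expect_equal(h1, h2, ignore_attr = TRUE)
})

test_that("greedy clumping keeps the best of correlated pairs and all independent ones", {
  coh <- small_cohort()
  g <- coh$genotypes
  # the most-correlated adjacent pair of block 1, plus a distant variant
  blk <- cor(g$dosage[, 1:10])^2
  diag(blk) <- 0
  top <- which(blk == max(blk), arr.ind = TRUE)[1L, ]
  ids <- g$variants$variant_id[c(top, 101)]
  r2 <- cor(g$dosage[, ids])^2
  expect_gt(r2[1, 2], 0.3)
  inst <- data.frame(analyte_id = "p", variant_id = ids,
                     p_exp = c(1e-10, 1e-9, 1e-5), stringsAsFactors = FALSE)
  out <- ld_clump(inst, g, r2_max = 0.3)
  expect_setequal(out$variant_id, ids[c(1, 3)])
  out01 <- ld_clump(inst, g, r2_max = 0.999)
  expect_equal(nrow(out01), 3L)
})

test_that("clumping equals a brute-force greedy oracle on a dense block", {
  coh <- small_cohort()
  g <- coh$genotypes
  ids <- g$variants$variant_id[1:20]   # two full LD blocks
  set.seed(3)
  p <- runif(20, 1e-12, 1e-6)
  inst <- data.frame(analyte_id = "p", variant_id = ids, p_exp = p,
                     stringsAsFactors = FALSE)
  r2 <- cor(g$dosage[, ids])^2
  for (r2max in c(0.01, 0.1, 0.3, 0.8)) {
    mine <- ld_clump(inst, g, r2_max = r2max)$variant_id
    oracle <- ids[brute_clump(p, r2, r2max)]
    expect_setequal(mine, oracle)
  }
})

test_that("the Wald ratio follows the stated arithmetic", {
  inst <- data.frame(analyte_id = "p", variant_id = "v", beta_exp = 0.5,
                     se_exp = 0.05, beta_out = 0.2, se_out = 0.05)
  est <- mr_wald(inst)
  expect_equal(est$beta, 0.4)
  expect_equal(est$se, 0.1)
  expect_equal(est$method, "Wald ratio")
  null_est <- mr_wald(transform(inst, beta_out = 0))
  expect_equal(null_est$beta, 0)
  expect_equal(null_est$p, 1)
  expect_error(mr_wald(transform(inst, beta_exp = 0)), "undefined")
})

test_that("IVW reduces to the weighted ratio mean with the stated fixed-effect SE", {
  insts <- data.frame(analyte_id = "p", variant_id = c("v1", "v2"),
                      beta_exp = c(0.5, 1), se_exp = 0.05,
                      beta_out = c(0.2, 0.2), se_out = c(0.05, 0.1))
  # ratios 0.4 and 0.2, both with first-order se 0.1
  est <- mr_ivw(insts, random = FALSE)
  expect_equal(est$beta, 0.3)
  expect_equal(est$se, 0.1 / sqrt(2))
  # multiplicative random effects only ever inflates
  est_re <- mr_ivw(insts, random = TRUE)
  expect_gte(est_re$se, est$se)
  # a single instrument is routed to the Wald ratio
  routed <- mr_ivw(insts[1, ])
  expect_equal(routed$method, "Wald ratio")
  expect_equal(routed$beta, 0.4)
})

test_that("the pleiotropy test is NA below 3 instruments and 1 for a perfect fit", {
  insts2 <- data.frame(analyte_id = "p", variant_id = c("v1", "v2"),
                       beta_exp = c(0.4, 0.6), se_exp = 0.05,
                       beta_out = c(0.12, 0.18), se_out = 0.05)
  expect_true(is.na(presso_global_test(insts2, n_sim = 200, seed = 1)))
  insts4 <- data.frame(analyte_id = "p", variant_id = paste0("v", 1:4),
                       beta_exp = c(0.4, 0.5, 0.6, 0.7), se_exp = 0.05,
                       beta_out = 0.3 * c(0.4, 0.5, 0.6, 0.7), se_out = 0.05)
  expect_equal(presso_global_test(insts4, n_sim = 200, seed = 1), 1)
  expect_warning(presso_global_test(insts4, n_sim = 50, seed = 1), "unstable")
})

test_that("a gross outlier instrument drives the pleiotropy p below 0.05", {
  set.seed(22)
  k <- 8
  be <- runif(k, 0.3, 0.7)
  insts <- data.frame(analyte_id = "p", variant_id = paste0("v", 1:k),
                      beta_exp = be, se_exp = 0.02,
                      beta_out = 0.2 * be + rnorm(k, 0, 0.02), se_out = 0.02)
  insts$beta_out[1] <- insts$beta_out[1] + 0.5
  expect_lt(presso_global_test(insts, n_sim = 500, seed = 2), 0.05)
})

test_that("the causal table applies BH across proteins and flags candidates", {
  mk <- function(id, p) structure(list(analyte_id = id, n_instruments = 2L,
                                       method = "IVW", beta = 0.1, se = 0.05,
                                       p = p, Q = 1, pleiotropy_p = NA_real_),
                                  class = "mr_estimate")
  tab <- causal_table(list(mk("a", 1), mk("b", 1), mk("c", 1)))
  expect_false(any(tab$causal_candidate))
  single <- causal_table(list(mk("a", 0.03)))
  expect_equal(single$fdr, single$p)
  expect_true(single$causal_candidate)
})

test_that("end-to-end MR recovers the simulated causal proteins", {
  coh <- small_cohort()
  norm <- log2_median_normalize(coh$proteome)
  bm <- combat_adjust(norm$values, coh$meta$plate,
                      covariates = data.frame(status = coh$meta$status,
                                              age = coh$meta$age))
  Y <- apply(bm$corrected, 2, inverse_normal_transform)
  w <- map_cis_windows(coh$proteome$analytes, coh$genotypes$variants)
  cov <- data.frame(age = coh$meta$age, sex = coh$meta$sex,
                    sub = coh$meta$subcohort, compute_pcs(bm$corrected, 4))
  sc <- scan_pqtl(Y, coh$genotypes, cov, w)
  tab <- run_mr(sc, coh$gwas, coh$genotypes, n_presso_sim = 200, seed = 5)
  truth <- coh$truth$analytes
  causal <- truth$analyte_id[truth$causal]
  expect_true(all(causal %in% tab$analyte_id[tab$causal_candidate]))
  # Wald ratio exactly when one instrument survived
  expect_true(all((tab$method == "Wald ratio") == (tab$n_instruments == 1L)))
  # pleiotropy p defined only from 3 instruments
  expect_true(all(is.na(tab$pleiotropy_p[tab$n_instruments < 3])))
})
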