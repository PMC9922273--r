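test_that("residualization removes covariates exactly", {
  set.seed(50)
  n <- 100
  cov <- data.frame(age = rnorm(n, 60, 10), sex = sample(c("M", "F"), n, TRUE),
                    center = sample(c("C1", "C2", "C3"), n, TRUE))
  Y <- matrix(rnorm(n * 10), n, 10, dimnames = list(paste0("s", 1:n), paste0("a", 1:10)))
  Y[, 1] <- 3 * cov$age            # fully explained by age
  res <- residualize(Y, cov)
  expect_lt(max(abs(res[, 1])), 1e-9)
  expect_lt(max(abs(colMeans(res))), 1e-10)
  for (j in 2:10)
    expect_lt(abs(cor(res[, j], cov$age)), 1e-10)
  # missing covariates drop the sample
  cov$age[5] <- NA
  expect_message(res2 <- residualize(Y, cov), "dropping 1")
  expect_equal(nrow(res2), n - 1L)
})

make_modular <- function(n = 200, blocks = 5, per = 10, w_range = c(0.6, 0.6),
                         seed = 51) {
  # factor model; w is the share of each analyte's variance explained by its
  # block factor, so a wide w_range plants hub structure
  set.seed(seed)
  f <- matrix(rnorm(n * blocks), n, blocks)
  x <- do.call(cbind, lapply(seq_len(blocks), function(b) {
    w <- runif(per, w_range[1], w_range[2])
    lam <- sqrt(w / (1 - w))
    f[, b] %*% t(lam) + matrix(rnorm(n * per), n, per)
  }))
  colnames(x) <- paste0("a", seq_len(blocks * per))
  scale(x)
}

test_that("soft-threshold diagnostics behave as the theory dictates", {
  x <- make_modular(n = 300, per = 30, w_range = c(0.1, 0.92))
  tab <- pick_soft_threshold(x, powers = c(1, 2, 4, 6, 8, 11))
  # connectivity shrinks monotonically with the exponent since |cor| <= 1
  expect_true(all(diff(tab$mean_k) < 0))
  # modular data reach a good scale-free fit at some power
  expect_gt(max(tab$rsq, na.rm = TRUE), 0.8)
  # independent noise at power 1: connectivity nearly uniform, poor fit
  set.seed(52)
  noise <- matrix(rnorm(500 * 60), 500, 60, dimnames = list(NULL, paste0("a", 1:60)))
  tn <- pick_soft_threshold(noise, powers = 1)
  expect_true(is.na(tn$rsq) || tn$rsq < 0.5)
  # spread of k under independence is a small fraction of its mean
  expect_lt((tn$max_k - tn$mean_k) / tn$mean_k, 0.5)
})

test_that("the TOM matches its defining formula and algebraic identities", {
  set.seed(53)
  # identical profiles: TOM exactly 1
  prof <- rnorm(50)
  trip <- cbind(a = prof, b = prof, c = prof) + 0
  tom3 <- tom_similarity(trip, network_config(power = 6))
  expect_equal(unname(tom3), matrix(1, 3, 3))
  # random instance equals direct elementwise evaluation
  x <- matrix(rnorm(40 * 5), 40, 5, dimnames = list(NULL, paste0("a", 1:5)))
  cfg <- network_config(power = 3)
  tom <- tom_similarity(x, cfg)
  a <- abs(cor(x))^3
  diag(a) <- 0
  k <- colSums(a)
  for (i in 1:5) for (j in 1:5) {
    if (i == j) next
    num <- sum(a[i, -c(i, j)] * a[-c(i, j), j]) + a[i, j]
    den <- min(k[i], k[j]) + 1 - a[i, j]
    expect_equal(tom[i, j], num / den, tolerance = 1e-12)
  }
  expect_error(tom_similarity(cbind(x, const = 1)), "constant analyte")
})

test_that("TOM identities hold across random instances and noise TOM is near zero", {
  for (s in 1:100) {
    set.seed(s)
    x <- matrix(rnorm(30 * 8), 30, 8, dimnames = list(NULL, paste0("a", 1:8)))
    tom <- tom_similarity(x, network_config(power = sample(2:12, 1)))
    expect_equal(tom, t(tom), tolerance = 1e-12)
    expect_true(all(diag(tom) == 1))
    expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
  }
  set.seed(101)
  big <- matrix(rnorm(2000 * 40), 2000, 40, dimnames = list(NULL, paste0("a", 1:40)))
  tomn <- tom_similarity(big, network_config(power = 6))
  expect_lt(max(tomn[upper.tri(tomn)]), 0.05)
})

test_that("planted blocks are recovered as modules and tiny clusters dissolve", {
  x <- make_modular(n = 300, blocks = 2, per = 40, w_range = c(0.7, 0.7),
                    seed = 54)
  noise <- matrix(rnorm(300 * 40), 300, 40, dimnames = list(NULL, paste0("n", 1:40)))
  dat <- cbind(x, noise)
  cfg <- network_config(power = 6, min_module_size = 30)
  modules <- detect_modules(tom_similarity(dat, cfg), cfg)
  expect_equal(length(attr(modules, "sizes")), 2L)
  planted <- rep(c(1, 2, 0), c(40, 40, 40))
  tab <- table(planted, modules)
  agreement <- (tab["1", "1"] + tab["2", "2"] + sum(tab["0", "0"])) / 120
  agreement <- max(agreement,
                   (tab["1", "2"] + tab["2", "1"] + sum(tab["0", "0"])) / 120)
  expect_gte(agreement, 0.95)
  # permuting analytes permutes, but does not change, the partition
  perm <- sample(ncol(dat))
  mod_p <- detect_modules(tom_similarity(dat[, perm], cfg), cfg)
  expect_equal(ari(mod_p, modules[perm]), 1)
  expect_equal(mod_p[order(names(mod_p))] > 0,
               modules[order(names(modules))] > 0)
  # an unreachable minimum size leaves everything unassigned
  cfg_big <- network_config(power = 6, min_module_size = 1000)
  expect_warning(none <- detect_modules(tom_similarity(dat, cfg), cfg_big),
                 "no module")
  expect_true(all(none == 0L))
})

test_that("degenerate consensus settings reduce to a single clustering's connectivity", {
  set.seed(55)
  x <- matrix(rnorm(30 * 4), 30, 4, dimnames = list(paste0("p", 1:30), NULL))
  cons <- consensus_cluster(x, k_max = 3, n_reps = 1, subsample = 1, seed = 1)
  cl <- cutree(hclust(dist(x), "average"), k = 2)
  expect_equal(unname(cons$consensus$k2), unname(outer(cl, cl, "==") * 1))
})

test_that("well-separated blobs give a crisp consensus and correct labels", {
  set.seed(56)
  truth <- rep(1:2, each = 40)
  x <- matrix(rnorm(80 * 6), 80, 6) + outer(as.numeric(truth == 2) * 4, rep(1, 6))
  rownames(x) <- paste0("p", 1:80)
  cons <- consensus_cluster(x, k_max = 4, n_reps = 50, seed = 2)
  cm <- cons$consensus$k2
  same <- outer(truth, truth, "==")
  diag(same) <- NA
  expect_gt(mean(cm[same & !is.na(same)]), 0.95)
  expect_lt(mean(cm[!same & !is.na(same)]), 0.05)
  expect_gt(ari(cons$labels[, "k2"], truth), 0.9)
  expect_equal(cons$k_best, 2L)
  # structural invariants
  expect_equal(cm, t(cm))
  expect_true(all(diag(cm) == 1))
  expect_true(all(cm >= 0 & cm <= 1))
})

test_that("clinical comparisons use the stated test per variable type", {
  set.seed(57)
  n <- 160
  lab <- rep(c(1, 2), each = n / 2)
  clin <- data.frame(age = rnorm(n, 61, 8), sex = sample(c("M", "F"), n, TRUE),
                     ptau = exp(rnorm(n, log(11) - 0.25 * (lab == 2) +
                                        0.25 * (lab == 1), 0.25)),
                     moca = round(rnorm(n, 27, 2)),
                     cat_var = sample(c("x", "y"), n, TRUE))
  res <- compare_endotypes_clinical(lab, clin,
                                    variables = c("age", "ptau", "moca", "cat_var"))
  expect_equal(res$test[res$variable == "age"], "mann_whitney")
  expect_equal(res$test[res$variable == "ptau"], "glm_age_sex_adjusted")
  expect_equal(res$test[res$variable == "cat_var"], "chi_squared")
  expect_lt(res$fdr[res$variable == "ptau"], 0.05)
  expect_equal(res$direction[res$variable == "ptau"], "lower in endotype 2")
  expect_gt(res$p[res$variable == "moca"], 0.05)
})

test_that("age/sex adjustment suppresses a confounded false positive", {
  set.seed(58)
  n <- 300
  sex <- sample(c("M", "F"), n, TRUE)
  # endotype associated with sex; variable driven by sex only
  lab <- ifelse(runif(n) < ifelse(sex == "M", 0.75, 0.25), 2, 1)
  y <- 2 * (sex == "M") + rnorm(n)
  clin <- data.frame(age = rnorm(n, 60, 8), sex = sex, y = y)
  res <- compare_endotypes_clinical(lab, clin, variables = "y")
  naive_p <- t.test(y ~ lab)$p.value
  expect_lt(naive_p, 0.01)
  expect_gt(res$p, 0.05)
})

test_that("protein scores are plain weighted sums with strict analyte checks", {
  vals <- matrix(1:12, 3, 4, dimnames = list(paste0("s", 1:3), paste0("a", 1:4)))
  expect_equal(unname(protein_score(c(a1 = 0, a2 = 0), vals)), c(0, 0, 0))
  expect_equal(unname(protein_score(c(a3 = 1), vals)), vals[, "a3"],
               ignore_attr = TRUE)
  w <- c(a1 = 0.5, a2 = -1, a4 = 2)
  expect_equal(unname(protein_score(w, vals)),
               as.numeric(vals[, names(w)] %*% w))
  expect_error(protein_score(c(zz = 1), vals), "missing from the matrix")
  expect_error(protein_score(numeric(0), vals), "empty weight set")
})

test_that("a separable p-tau threshold yields a single perfect split", {
  set.seed(59)
  n <- 200
  lab <- rep(c(1, 2), each = n / 2)
  ptau <- ifelse(lab == 1, runif(n, 12, 18), runif(n, 5, 10))
  clin <- data.frame(ptau = ptau, moca = rnorm(n, 27, 2),
                     updrs1 = rpois(n, 5))
  tree <- train_endotype_tree(clin, lab, seed = 3)
  expect_equal(tree$n_splits, 1L)
  expect_equal(tree$splits$variable, "ptau")
  expect_gt(tree$splits$threshold, 10)
  expect_lt(tree$splits$threshold, 12)
  expect_equal(tree$accuracy_test, 1)
  expect_equal(tree$auc_test, 1)
})

test_that("labels independent of the predictors prune to the root", {
  set.seed(60)
  n <- 300
  lab <- rep(c(1, 2), c(160, 140))
  clin <- data.frame(ptau = rnorm(n, 11, 2), moca = rnorm(n, 27, 2),
                     abeta = rnorm(n, 850, 150))
  tree <- train_endotype_tree(clin, lab, seed = 4)
  expect_equal(tree$n_splits, 0L)
  maj <- max(table(lab[tree$test_idx])) / length(tree$test_idx)
  expect_equal(tree$accuracy_test, maj, tolerance = 0.15)
})

test_that("the CV-chosen subtree is nested in the full tree and within 1 SE of the CV minimum", {
  for (s in 1:5) {
    set.seed(s)
    n <- 200
    lab <- rep(c(1, 2), each = n / 2)
    x <- data.frame(a = rnorm(n) + 0.8 * (lab == 2), b = rnorm(n), c = rnorm(n))
    tr <- train_endotype_tree(x, lab, seed = s)
    cp <- tr$tree$cptable
    chosen <- cp[nrow(cp), "xerror"]
    best <- which.min(cp[, "xerror"])
    expect_lte(chosen, cp[best, "xerror"] + cp[best, "xstd"] + 1e-9)
    # pruning only ever removes splits relative to the grown tree
    expect_lte(tr$n_splits, cp[nrow(cp), "nsplit"] + 1)
  }
})

test_that("the full discovery pipeline recovers the planted endotypes", {
  cfg <- sim_config(n_samples = 600, n_variants = 100, n_analytes = 150,
                    ld_block_size = 10, seed = 61)
  coh <- simulate_cohort(cfg)
  bm <- combat_adjust(coh$proteome$values, coh$meta$plate,
                      covariates = data.frame(status = coh$meta$status))
  ef <- discover_endotypes(bm$corrected, coh$meta, seed = 7)
  truth <- coh$truth$samples$endotype[match(ef$sample_ids,
                                            coh$truth$samples$sample_id)]
  expect_gt(ari(ef$labels, truth), 0.8)
  expect_equal(ef$consensus$k_best, 2L)
  # the detected module analytes are the planted ones (the two strongly
  # endotype-coupled modules may be reported merged, never mixed with noise)
  planted <- coh$truth$analytes$module
  found <- ef$modules[coh$truth$analytes$analyte_id]
  expect_true(all(found[planted == 0] == 0))
  expect_gt(mean(found[planted > 0] > 0), 0.95)
})
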