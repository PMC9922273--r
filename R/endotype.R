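#' Network configuration for co-expression module detection
#'
#' @param power soft-threshold exponent on `|cor|`; 11 by default, the
#'   setting used for the full-scale aptamer panel.
#' @param min_module_size smallest retained module. The full-panel setting
#'   is 500 (of ~4785 aptamers); at synthetic scale the default adapts as
#'   `max(15, 0.1 * n_analytes)` when `NULL` is passed to
#'   [detect_modules()].
#' @param cut_height static tree-cut height on the 1 - TOM dendrogram;
#'   0.99 by default (uncorrelated analytes have topological overlap near 0
#'   and merge at dissimilarity near 1, so they dissolve while correlated
#'   modules, which merge well below the cut, survive).
#' @return an object of class `network_config`.
#' @export
network_config <- function(power = 11, min_module_size = NULL,
                           cut_height = 0.99) {
  if (power < 1) stop("power must be >= 1")
  if (!is.null(min_module_size) && min_module_size < 2)
    stop("min_module_size must be >= 2")
  structure(list(power = power, min_module_size = min_module_size,
                 cut_height = cut_height), class = "network_config")
}

#' Residualize a proteome on nuisance covariates
#'
#' Per-analyte OLS residuals on age, sex and study centre (or any supplied
#' covariate set); the covariate design includes an intercept so residual
#' column means are zero. Samples with missing covariates are dropped with
#' a message.
#'
#' @param values samples x analytes matrix.
#' @param covariates data.frame of covariates aligned with rows of `values`.
#' @return residual matrix (possibly fewer rows), class-free.
#' @export
residualize <- function(values, covariates) {
  check_matrix(values, "values")
  covariates <- as.data.frame(covariates)
  ok <- stats::complete.cases(covariates)
  if (any(!ok)) message("dropping ", sum(!ok), " sample(s) with missing covariates")
  X <- stats::model.matrix(~ ., data = covariates[ok, , drop = FALSE])
  res <- qr.resid(qr(X), values[ok, , drop = FALSE])
  dimnames(res) <- list(rownames(values)[ok], colnames(values))
  res
}

#' Scale-free topology diagnostics over candidate soft thresholds
#'
#' For each candidate power the unsigned adjacency `|cor|^power` is formed,
#' per-analyte connectivity `k_i = sum_{u != i} a_iu` computed, and the
#' scale-free fit measured as the R^2 of the `log10 p(k)` versus
#' `log10 k` regression over occupied connectivity bins. Powers whose
#' connectivity distribution occupies fewer than 10 bins are flagged and
#' not fitted.
#'
#' @param residuals samples x analytes matrix.
#' @param powers candidate exponents.
#' @param n_bins histogram bins for the degree distribution.
#' @return data.frame: power, rsq, slope, mean_k, median_k, max_k, fitted.
#' @export
pick_soft_threshold <- function(residuals, powers = c(1:10, 11, 12, 14, 16, 18, 20),
                                n_bins = 10L) {
  if (ncol(residuals) < 20L) stop("need at least 20 analytes")
  ac <- abs(stats::cor(residuals))
  diag(ac) <- 0
  out <- lapply(powers, function(p) {
    k <- colSums(ac^p)
    brk <- seq(min(k), max(k), length.out = n_bins + 1L)
    bin <- cut(k, brk, include.lowest = TRUE)
    freq <- table(bin)
    occ <- freq > 0
    if (sum(occ) < n_bins) {
      return(data.frame(power = p, rsq = NA_real_, slope = NA_real_,
                        mean_k = mean(k), median_k = stats::median(k),
                        max_k = max(k), fitted = FALSE))
    }
    kmid <- tapply(k, bin, mean)[occ]
    lp <- log10(as.numeric(freq[occ]) / length(k))
    lk <- log10(pmax(kmid, .Machine$double.eps))
    fit <- stats::lm(lp ~ lk)
    data.frame(power = p, rsq = summary(fit)$r.squared,
               slope = stats::coef(fit)[2L],
               mean_k = mean(k), median_k = stats::median(k), max_k = max(k),
               fitted = TRUE, row.names = NULL)
  })
  do.call(rbind, out)
}

#' Unsigned topological overlap matrix
#'
#' Adjacency `a_ij = |cor(x_i, x_j)|^power` and topological overlap
#' `TOM_ij = (sum_{u != i,j} a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 -
#' a_ij)` with unit diagonal. Entries lie in `[0, 1]`; identical profiles
#' give TOM exactly 1.
#'
#' @param residuals samples x analytes matrix; constant analytes are an
#'   error (their correlation is undefined).
#' @param config a [network_config()] (only `power` is used).
#' @return analytes x analytes TOM matrix.
#' @export
tom_similarity <- function(residuals, config = network_config()) {
  sds <- apply(residuals, 2L, stats::sd)
  if (any(sds == 0))
    stop("constant analyte(s): ",
         paste(utils::head(colnames(residuals)[sds == 0], 5L), collapse = ", "))
  a <- abs(stats::cor(residuals))^config$power
  diag(a) <- 0
  k <- colSums(a)
  num <- a %*% a + a
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  diag(tom) <- 1
  dimnames(tom) <- list(colnames(residuals), colnames(residuals))
  tom
}

#' Detect co-expression modules from a TOM
#'
#' Average-linkage hierarchical clustering of `1 - TOM` with a static cut:
#' clusters below the minimum module size are dissolved to "unassigned"
#' (module 0), and surviving modules are relabelled 1, 2, ... by
#' decreasing size.
#'
#' @param tom TOM matrix from [tom_similarity()].
#' @param config a [network_config()]; `min_module_size = NULL` adapts as
#'   `max(15, 0.1 * n_analytes)`.
#' @return integer vector of module labels (0 = unassigned) named by
#'   analyte, with attribute `sizes`.
#' @export
detect_modules <- function(tom, config = network_config()) {
  min_size <- config$min_module_size %||% max(15, round(0.1 * ncol(tom)))
  h <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  cut_h <- config$cut_height %||% 0.99
  raw <- stats::cutree(h, h = cut_h)
  sizes <- table(raw)
  keep <- names(sizes)[sizes >= min_size]
  if (!length(keep)) {
    warning("no module reaches the minimum size; all analytes unassigned")
    out <- stats::setNames(rep(0L, ncol(tom)), colnames(tom))
    attr(out, "sizes") <- integer(0)
    return(out)
  }
  keep <- keep[order(-sizes[keep])]
  out <- integer(ncol(tom))
  for (i in seq_along(keep)) out[raw == as.integer(keep[i])] <- i
  names(out) <- colnames(tom)
  attr(out, "sizes") <- as.integer(sizes[keep])
  out
}

#' Consensus clustering of patients
#'
#' Repeatedly subsamples patients, clusters each subsample (hierarchical,
#' Euclidean distance, average linkage) into k groups for every k up to
#' `k_max`, and records for each patient pair the fraction of co-sampled
#' replicates in which they co-cluster. Final labels per k come from
#' hierarchical clustering of `1 - consensus`; the consensus CDF, its
#' area and the Delta-area criterion are reported along with a tracking
#' table of assignments across k. Additional replicates are drawn if any
#' pair was never co-sampled, so every consensus entry is a valid
#' proportion.
#'
#' @param features patients x features matrix (e.g. the module analytes of
#'   the residualized proteome).
#' @param k_max largest number of clusters considered (>= 2).
#' @param n_reps subsampling replicates.
#' @param subsample fraction of patients per replicate.
#' @param seed integer seed.
#' @return object of class `consensus_result`: `consensus` (list of
#'   patient x patient matrices per k), `labels` (patients x k-1 tracking
#'   matrix), `cdf_area`, `delta_area`, `k_best`.
#' @export
consensus_cluster <- function(features, k_max = 6L, n_reps = 100L,
                              subsample = 0.8, seed = 1L) {
  check_matrix(features, "features")
  if (k_max < 2L) stop("k_max must be >= 2")
  n <- nrow(features)
  if (n < 2L * k_max) stop("need at least 2 * k_max patients")
  set.seed(seed)
  ks <- 2:k_max
  m <- round(subsample * n)
  cosample <- matrix(0, n, n)
  cocluster <- lapply(ks, function(k) matrix(0, n, n))
  run_rep <- function() {
    idx <- sort(sample.int(n, m))
    hc <- stats::hclust(stats::dist(features[idx, , drop = FALSE]),
                        method = "average")
    cosample[idx, idx] <<- cosample[idx, idx] + 1
    for (ki in seq_along(ks)) {
      cl <- stats::cutree(hc, k = ks[ki])
      same <- outer(cl, cl, "==")
      cocluster[[ki]][idx, idx] <<- cocluster[[ki]][idx, idx] + same
    }
  }
  for (r in seq_len(n_reps)) run_rep()
  extra <- 0L
  while (any(cosample[upper.tri(cosample)] == 0) && extra < 200L) {
    run_rep()
    extra <- extra + 1L
  }
  consensus <- lapply(cocluster, function(cc) {
    cm <- cc / pmax(cosample, 1)
    diag(cm) <- 1
    dimnames(cm) <- list(rownames(features), rownames(features))
    cm
  })
  names(consensus) <- paste0("k", ks)

  labels <- sapply(seq_along(ks), function(ki) {
    hc <- stats::hclust(stats::as.dist(1 - consensus[[ki]]), method = "average")
    stats::cutree(hc, k = ks[ki])
  })
  dimnames(labels) <- list(rownames(features), paste0("k", ks))

  grid <- seq(0, 1, length.out = 101L)
  cdf_area <- vapply(consensus, function(cm) {
    v <- cm[upper.tri(cm)]
    cdf <- stats::ecdf(v)(grid)
    sum(diff(grid) * cdf[-length(cdf)])
  }, 0)
  delta_area <- c(cdf_area[1L],
                  diff(cdf_area) / cdf_area[-length(cdf_area)])
  names(delta_area) <- names(cdf_area)
  structure(list(consensus = consensus, labels = labels,
                 cdf_area = cdf_area, delta_area = delta_area,
                 k_best = ks[which.max(delta_area)],
                 k_values = ks),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("consensus_result: %d patients, k = %d..%d (Delta-area best: k = %d)\n",
              nrow(x$labels), min(x$k_values), max(x$k_values), x$k_best))
  print(round(x$delta_area, 3))
  invisible(x)
}

#' Compare clinical variables between endotypes
#'
#' Categorical variables are tested with a two-sided chi-squared test
#' (Fisher's exact test when an expected cell count falls below 1);
#' quantitative variables with a Gaussian GLM adjusted for age and sex,
#' testing the endotype coefficient; age itself with a two-sided
#' Mann-Whitney U test. Directions are reported relative to endotype 2.
#'
#' @param labels endotype labels (2 levels), one per patient.
#' @param clinical data.frame of clinical variables with `age` and `sex`
#'   columns available for adjustment.
#' @param variables columns to test; defaults to all except age/sex.
#' @return data.frame: variable, test, estimate (endotype-2 effect), p,
#'   fdr, direction.
#' @export
compare_endotypes_clinical <- function(labels, clinical,
                                       variables = setdiff(colnames(clinical),
                                                           c("age", "sex"))) {
  labels <- factor(labels)
  if (nlevels(labels) != 2L) stop("expected exactly 2 endotypes")
  if (any(table(labels) < 5L)) stop("each endotype needs at least 5 patients")
  e2 <- labels == levels(labels)[2L]
  rows <- lapply(variables, function(v) {
    x <- clinical[[v]]
    if (is.character(x) || is.factor(x) || is.logical(x)) {
      tabx <- table(labels, x)
      expd <- outer(rowSums(tabx), colSums(tabx)) / sum(tabx)
      if (any(expd < 1)) {
        p <- stats::fisher.test(tabx)$p.value
        test <- "fisher_exact"
      } else {
        p <- suppressWarnings(stats::chisq.test(tabx)$p.value)
        test <- "chi_squared"
      }
      est <- NA_real_
    } else if (identical(v, "age")) {
      p <- stats::wilcox.test(x ~ labels)$p.value
      est <- stats::median(x[e2]) - stats::median(x[!e2])
      test <- "mann_whitney"
    } else {
      d <- data.frame(y = x, e2 = as.numeric(e2), age = clinical$age,
                      sex = clinical$sex)
      fit <- stats::glm(y ~ e2 + age + sex, data = d)
      sm <- summary(fit)$coefficients
      est <- sm["e2", 1L]
      p <- sm["e2", 4L]
      test <- "glm_age_sex_adjusted"
    }
    data.frame(variable = v, test = test, estimate = est, p = p,
               direction = if (is.na(est)) NA_character_
               else if (est < 0) "lower in endotype 2" else "higher in endotype 2",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_fdr(out$p)
  rownames(out) <- NULL
  out
}

#' Linear protein score
#'
#' Weighted sum of analyte abundances per sample, `score_s = sum_a w_a
#' x_sa`, for externally supplied weights (e.g. a published proteomic risk
#' score).
#'
#' @param weights named numeric vector mapping analyte ids to weights.
#' @param proteome a `protein_matrix` or samples x analytes matrix.
#' @return named numeric vector of per-sample scores.
#' @export
protein_score <- function(weights, proteome) {
  if (!length(weights)) stop("empty weight set")
  vals <- if (inherits(proteome, "protein_matrix")) proteome$values else proteome
  missing <- setdiff(names(weights), colnames(vals))
  if (length(missing))
    stop("analytes missing from the matrix: ", paste(missing, collapse = ", "))
  drop(vals[, names(weights), drop = FALSE] %*% weights)
}

#' Train a pruned classification tree predicting endotype
#'
#' CART (Gini impurity) on clinical predictors only, grown on a stratified
#' 70% training split and pruned along the cost-complexity path by 10-fold
#' cross-validation; by default the one-standard-error rule picks the
#' smallest subtree whose CV error is within 1 SE of the minimum. Reports
#' training and held-out test accuracy and the test AUC computed from leaf
#' class proportions.
#'
#' @param clinical data.frame of clinical predictors (no proteomic
#'   features), one row per patient.
#' @param labels endotype labels (2 levels).
#' @param train_frac training fraction (0.7).
#' @param cv_folds cross-validation folds for pruning (10).
#' @param cv_reps repeats of the cross-validation whose error curves are
#'   averaged before the pruning rule is applied; repetition damps the
#'   fold-assignment noise of a single CV run so the selected subtree is
#'   stable (7 by default).
#' @param seed integer seed controlling the split and the CV folds.
#' @param one_se use the 1-SE pruning rule (default) rather than the raw
#'   CV minimum.
#' @return object of class `endotype_tree`: the pruned `rpart` tree,
#'   `splits` (variable/threshold of each split), accuracy_train,
#'   accuracy_test, auc_test, and the split indices.
#' @export
train_endotype_tree <- function(clinical, labels, train_frac = 0.7,
                                cv_folds = 10L, cv_reps = 7L, seed = 1L,
                                one_se = TRUE) {
  labels <- factor(labels)
  if (length(labels) != nrow(clinical)) stop("labels and clinical rows differ")
  if (length(labels) < 50L) stop("need at least 50 labelled patients")
  set.seed(seed)
  train_idx <- sort(unlist(lapply(split(seq_along(labels), labels), function(ix)
    ix[sample.int(length(ix), round(train_frac * length(ix)))])))
  test_idx <- setdiff(seq_along(labels), train_idx)
  d <- data.frame(.endotype = labels, clinical)

  if (nlevels(droplevels(labels[train_idx])) < 2L) {
    warning("single-class training labels; returning a no-split tree")
    fit <- NULL
  } else {
    grow <- function() rpart::rpart(.endotype ~ .,
                                    data = d[train_idx, , drop = FALSE],
                                    method = "class",
                                    parms = list(split = "gini"),
                                    control = rpart::rpart.control(cp = 0,
                                                                   xval = cv_folds,
                                                                   minsplit = 20L))
    fit <- grow()
    cp <- fit$cptable
    if (cv_reps > 1L && nrow(cp) > 1L) {
      # the grown tree is deterministic; only the CV curves are re-drawn
      xe <- cp[, "xerror"]
      xs <- cp[, "xstd"]
      for (r in seq_len(cv_reps - 1L)) {
        cpr <- grow()$cptable
        xe <- xe + cpr[, "xerror"]
        xs <- xs + cpr[, "xstd"]
      }
      cp[, "xerror"] <- xe / cv_reps
      cp[, "xstd"] <- xs / cv_reps
    }
    best <- which.min(cp[, "xerror"])
    if (one_se) {
      thr <- cp[best, "xerror"] + cp[best, "xstd"]
      best <- which(cp[, "xerror"] <= thr)[1L]
    }
    fit <- rpart::prune(fit, cp = cp[best, "CP"])
    fit$cptable <- cp[seq_len(best), , drop = FALSE]
  }
  predict_class <- function(idx) {
    if (is.null(fit) || nrow(fit$frame) == 1L) {
      maj <- names(which.max(table(labels[train_idx])))
      factor(rep(maj, length(idx)), levels = levels(labels))
    } else {
      stats::predict(fit, d[idx, , drop = FALSE], type = "class")
    }
  }
  prob2 <- function(idx) {
    if (is.null(fit) || nrow(fit$frame) == 1L)
      rep(mean(labels[train_idx] == levels(labels)[2L]), length(idx))
    else stats::predict(fit, d[idx, , drop = FALSE])[, levels(labels)[2L]]
  }
  acc <- function(idx) mean(predict_class(idx) == labels[idx])
  splits <- if (!is.null(fit) && nrow(fit$frame) > 1L) {
    # primary split of each internal node: rpart lists primary, then
    # competing, then surrogate rows per node in frame order
    fr <- fit$frame
    ii <- which(fr$var != "<leaf>")
    nrows <- fr$ncompete[ii] + fr$nsurrogate[ii] + 1L
    start <- cumsum(c(1L, utils::head(nrows, -1L)))
    data.frame(variable = rownames(fit$splits)[start],
               threshold = fit$splits[start, "index"],
               row.names = NULL, stringsAsFactors = FALSE)
  } else data.frame(variable = character(0), threshold = numeric(0))
  structure(list(tree = fit, splits = splits,
                 n_splits = if (is.null(fit)) 0L else sum(fit$frame$var != "<leaf>"),
                 accuracy_train = acc(train_idx),
                 accuracy_test = acc(test_idx),
                 auc_test = rank_auc(prob2(test_idx),
                                     labels[test_idx] == levels(labels)[2L]),
                 train_idx = train_idx, test_idx = test_idx,
                 levels = levels(labels)),
            class = "endotype_tree")
}

#' @export
print.endotype_tree <- function(x, ...) {
  cat(sprintf("endotype_tree: %d split(s); accuracy train %.3f / test %.3f; test AUC %.3f\n",
              x$n_splits, x$accuracy_train, x$accuracy_test, x$auc_test))
  if (x$n_splits > 0) {
    cat("  primary split:", x$splits$variable[1L], "at",
        signif(x$splits$threshold[1L], 4), "\n")
  }
  invisible(x)
}

#' Full endotype discovery pipeline on idiopathic patients
#'
#' Residualizes the idiopathic patients' proteome on age, sex and centre,
#' builds the soft-thresholded unsigned TOM, detects co-expression
#' modules, consensus-clusters patients on the module analytes, and
#' returns the endotype labels at `k` (2 by default, the configuration
#' carried forward to clinical characterization).
#'
#' @param values samples x analytes matrix (normalized, batch-corrected).
#' @param meta `sample_meta`; idiopathic patients are
#'   `subcohort == "none" & status == "case"`.
#' @param config a [network_config()].
#' @param k number of endotypes to report (2 default).
#' @param n_reps,subsample,seed consensus-clustering settings.
#' @return object of class `endotype_fit`: residuals, modules, consensus
#'   result, per-patient endotype labels, the module analyte set.
#' @export
discover_endotypes <- function(values, meta, config = network_config(),
                               k = 2L, n_reps = 100L, subsample = 0.8,
                               seed = 1L) {
  idio <- which(meta$subcohort == "none" & meta$status == "case")
  if (length(idio) < 2L * k) stop("not enough idiopathic patients")
  res <- residualize(values[idio, , drop = FALSE],
                     meta[idio, c("age", "sex", "center")])
  tom <- tom_similarity(res, config)
  modules <- detect_modules(tom, config)
  mod_analytes <- names(modules)[modules > 0]
  if (!length(mod_analytes)) stop("no co-expression module detected")
  cons <- consensus_cluster(res[, mod_analytes, drop = FALSE],
                            k_max = max(6L, k), n_reps = n_reps,
                            subsample = subsample, seed = seed)
  labels <- cons$labels[, paste0("k", k)]
  structure(list(residuals = res, modules = modules, consensus = cons,
                 labels = labels, module_analytes = mod_analytes,
                 sample_ids = meta$sample_id[idio], k = k),
            class = "endotype_fit")
}

#' @export
print.endotype_fit <- function(x, ...) {
  cat(sprintf("endotype_fit: %d idiopathic patients, %d module analytes in %d module(s)\n",
              length(x$labels), length(x$module_analytes),
              length(attr(x$modules, "sizes"))))
  cat("  endotype sizes:", paste(table(x$labels), collapse = " / "), "\n")
  invisible(x)
}

#' Write endotype discovery outputs as TSV files
#'
#' Exports the module assignments, the per-patient endotype labels, the
#' consensus matrix at the chosen k, and the label tracking table across k.
#'
#' @param fit an `endotype_fit` from [discover_endotypes()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_endotype_tsv <- function(fit, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.table(data.frame(analyte_id = names(fit$modules),
                                module = as.integer(fit$modules)),
                     file.path(dir, "modules.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(sample_id = fit$sample_ids,
                                endotype = as.integer(fit$labels)),
                     file.path(dir, "endotype_labels.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cm <- fit$consensus$consensus[[paste0("k", fit$k)]]
  utils::write.table(data.frame(sample_id = rownames(cm), cm,
                                check.names = FALSE),
                     file.path(dir, "consensus_matrix.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(sample_id = rownames(fit$consensus$labels),
                                fit$consensus$labels, check.names = FALSE),
                     file.path(dir, "tracking.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
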