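#' Median normalization by dilution group on log2 scale
#'
#' Equalizes the per-sample median signal within each dilution group to the
#' group's overall median, the standard total-signal normalization for
#' aptamer panels where analytes are assayed at different dilutions.
#'
#' @param proteome a `protein_matrix`; `values` must be on log2 scale unless
#'   `log2 = FALSE`, in which case strictly positive raw values are log2
#'   transformed first.
#' @param log2 set `FALSE` for raw (pre-log) input.
#' @return the normalized `protein_matrix`.
#' @export
log2_median_normalize <- function(proteome, log2 = TRUE) {
  vals <- proteome$values
  check_matrix(vals, "proteome values")
  if (!log2) {
    if (any(vals <= 0)) {
      bad <- which(vals <= 0, arr.ind = TRUE)[1L, ]
      stop(sprintf("nonpositive raw value at sample '%s', analyte '%s'",
                   rownames(vals)[bad[1]], colnames(vals)[bad[2]]))
    }
    vals <- base::log2(vals)
  }
  for (g in unique(proteome$analytes$dilution)) {
    cols <- which(proteome$analytes$dilution == g)
    sub <- vals[, cols, drop = FALSE]
    sample_med <- apply(sub, 1L, stats::median)
    vals[, cols] <- sub - sample_med + stats::median(sub)
  }
  proteome$values <- vals
  proteome
}

#' Parametric empirical-Bayes batch correction
#'
#' Location/scale batch adjustment in the canonical parametric
#' empirical-Bayes (ComBat) formulation: per analyte the data are
#' standardized against a grand mean plus covariate fit, per-batch
#' location (gamma) and scale (delta^2) parameters are estimated,
#' shrunk towards moment-matched conjugate priors (normal for location,
#' inverse-gamma for scale) by iterating the conditional posterior means to
#' convergence, and removed before back-transforming. Biological covariates
#' supplied in `covariates` are preserved.
#'
#' @param values samples x analytes numeric matrix (log2 scale).
#' @param batch factor/character of batch (plate) labels, one per sample.
#' @param covariates optional data.frame or model matrix of biological
#'   covariates to protect (no intercept needed).
#' @param tol convergence tolerance of the EB iteration.
#' @param max_iter iteration cap.
#' @return list of class `batch_model`: `corrected` (adjusted matrix) and
#'   the model internals (`gamma_star`, `delta_star` per batch x analyte,
#'   prior hyperparameters).
#' @export
combat_adjust <- function(values, batch, covariates = NULL,
                          tol = 1e-6, max_iter = 200L) {
  check_matrix(values, "values")
  batch <- factor(batch)
  if (length(batch) != nrow(values))
    stop("batch labels and rows of `values` differ in length")
  nb <- table(batch)
  if (any(nb < 2L))
    stop("singleton batch(es): ", paste(names(nb)[nb < 2], collapse = ", "),
         "; each batch needs at least 2 samples")
  B <- nlevels(batch)
  n <- nrow(values)

  if (B == 1L) {
    return(structure(list(corrected = values, gamma_star = NULL,
                          delta_star = NULL, hyper = NULL,
                          batch = batch), class = "batch_model"))
  }

  batch_design <- stats::model.matrix(~ 0 + batch)
  X <- batch_design
  if (!is.null(covariates)) {
    C <- if (is.matrix(covariates)) covariates
    else stats::model.matrix(~ ., data = as.data.frame(covariates))[, -1, drop = FALSE]
    X <- cbind(batch_design, C)
    if (qr(X)$rank < ncol(X))
      stop("covariates are confounded with batch (combined design is rank deficient); ",
           "refusing to adjust")
  }
  fit <- stats::lm.fit(X, values)
  bhat <- fit$coefficients
  grand <- crossprod(nb / n, bhat[seq_len(B), , drop = FALSE])  # weighted batch means
  stand_mean <- matrix(grand, n, ncol(values), byrow = TRUE)
  if (ncol(X) > B)
    stand_mean <- stand_mean +
      X[, -(seq_len(B)), drop = FALSE] %*% bhat[-(seq_len(B)), , drop = FALSE]
  var_pooled <- colSums((values - X %*% bhat)^2) / n
  sd_pooled <- sqrt(var_pooled)
  s <- sweep(values - stand_mean, 2L, sd_pooled, "/")

  # batch location/scale estimates on the standardized scale
  gamma_hat <- apply(s, 2L, function(col) tapply(col, batch, mean))
  delta_hat <- apply(s, 2L, function(col) tapply(col, batch, stats::var))
  gamma_bar <- rowMeans(gamma_hat)
  t2 <- apply(gamma_hat, 1L, stats::var)
  # inverse-gamma moments for delta^2
  dmean <- rowMeans(delta_hat)
  dvar <- apply(delta_hat, 1L, stats::var)
  a_prior <- (2 * dvar + dmean^2) / dvar
  b_prior <- (dmean * dvar + dmean^3) / dvar

  gamma_star <- gamma_hat
  delta_star <- delta_hat
  for (b in seq_len(B)) {
    idx <- which(batch == levels(batch)[b])
    nbb <- length(idx)
    g <- gamma_hat[b, ]; dl <- delta_hat[b, ]
    g_old <- g; d_old <- dl
    sums2 <- function(gv) colSums((s[idx, , drop = FALSE] -
                                     matrix(gv, nbb, ncol(s), byrow = TRUE))^2)
    for (it in seq_len(max_iter)) {
      g_new <- (nbb * t2[b] * gamma_hat[b, ] + d_old * gamma_bar[b]) /
        (nbb * t2[b] + d_old)
      d_new <- (0.5 * sums2(g_new) + b_prior[b]) / (nbb / 2 + a_prior[b] - 1)
      change <- max(abs(g_new - g_old) / pmax(abs(g_old), 1e-12),
                    abs(d_new - d_old) / pmax(abs(d_old), 1e-12))
      g_old <- g_new; d_old <- d_new
      if (change < tol) break
    }
    gamma_star[b, ] <- g_old
    delta_star[b, ] <- d_old
    s[idx, ] <- sweep(sweep(s[idx, , drop = FALSE], 2L, g_old, "-"),
                      2L, sqrt(d_old), "/")
  }
  corrected <- sweep(s, 2L, sd_pooled, "*") + stand_mean
  dimnames(corrected) <- dimnames(values)
  structure(list(corrected = corrected, gamma_star = gamma_star,
                 delta_star = delta_star,
                 hyper = list(gamma_bar = gamma_bar, t2 = t2,
                              a_prior = a_prior, b_prior = b_prior),
                 batch = batch), class = "batch_model")
}

#' @export
print.batch_model <- function(x, ...) {
  if (is.null(x$gamma_star)) {
    cat("batch_model: single batch, identity adjustment\n")
  } else {
    cat(sprintf("batch_model: %d batches x %d analytes adjusted (EB location/scale)\n",
                nrow(x$gamma_star), ncol(x$gamma_star)))
    cat(sprintf("  mean |gamma*| = %.3f, mean delta* = %.3f\n",
                mean(abs(x$gamma_star)), mean(x$delta_star)))
  }
  invisible(x)
}

#' Principal component scores
#'
#' Column-centred SVD scores ordered by decreasing variance explained, with
#' a deterministic sign convention (the largest-magnitude loading of each
#' component is positive).
#'
#' @param data samples x features numeric matrix.
#' @param k number of components, `k < min(dim(data))`.
#' @return samples x k score matrix with attribute `var_explained`.
#' @export
compute_pcs <- function(data, k) {
  check_matrix(data, "data")
  if (k >= min(dim(data))) stop("k must be smaller than both dimensions of `data`")
  x <- scale(data, center = TRUE, scale = FALSE)
  sv <- svd(x, nu = k, nv = k)
  flip <- vapply(seq_len(k), function(j) {
    v <- sv$v[, j]
    if (v[which.max(abs(v))] < 0) -1 else 1
  }, 0)
  scores <- sweep(sv$u %*% diag(sv$d[seq_len(k)], k), 2L, flip, "*")
  rownames(scores) <- rownames(data)
  colnames(scores) <- paste0("PC", seq_len(k))
  attr(scores, "var_explained") <- sv$d^2 / sum(sv$d^2)
  scores
}
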