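#' Fit per-analyte linear models over one shared design
#'
#' Ordinary least squares of every analyte on a common design matrix via a
#' single QR decomposition. Returns the ingredients of moderated-t
#' inference: coefficients, unscaled coefficient standard deviations,
#' per-analyte residual variances and the shared residual degrees of
#' freedom.
#'
#' @param values samples x analytes matrix (log2 scale).
#' @param design model matrix (with intercept) or data.frame of covariates.
#' @return list of class `lm_fit`: `coefficients` (p x analytes),
#'   `stdev_unscaled` (p, sqrt of diagonal of `(X'X)^-1`), `sigma2`
#'   (per-analyte residual variance), `df` (residual df), `design`, `qr`.
#' @export
fit_linear_models <- function(values, design) {
  check_matrix(values, "values")
  X <- if (is.matrix(design)) design
  else stats::model.matrix(~ ., data = as.data.frame(design))
  if (nrow(X) != nrow(values)) stop("design and values have different sample counts")
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    aliased <- colnames(X)[qx$pivot[-seq_len(qx$rank)]]
    stop("design is rank deficient; aliased columns: ",
         paste(aliased, collapse = ", "))
  }
  df <- nrow(X) - qx$rank
  if (df < 2L) stop("fewer than 2 residual degrees of freedom")
  coef <- qr.coef(qx, values)
  res <- qr.resid(qx, values)
  sigma2 <- colSums(res^2) / df
  xtxinv <- chol2inv(qr.R(qx)[seq_len(qx$rank), seq_len(qx$rank)])
  stdev_unscaled <- numeric(ncol(X))
  stdev_unscaled[qx$pivot] <- sqrt(diag(xtxinv))
  names(stdev_unscaled) <- colnames(X)
  structure(list(coefficients = coef,
                 stdev_unscaled = stdev_unscaled,
                 sigma2 = sigma2, df = df, design = X, qr = qx),
            class = "lm_fit")
}

# Newton inversion of the trigamma function (solve trigamma(x) = y, y > 0)
trigamma_inverse <- function(y) {
  vapply(y, function(yy) {
    if (!is.finite(yy) || yy <= 0) return(Inf)
    x <- 0.5 + 1 / yy
    for (i in 1:60) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / yy) / psigamma(x, deriv = 2L)
      x <- x + dif
      if (!is.finite(x) || x <= 0) return(Inf)
      if (abs(dif) / x < 1e-10) break
    }
    x
  }, 0)
}

#' Empirical-Bayes hyperparameters of the variance prior
#'
#' Moment-matches a scaled inverse chi-square prior `s0^2 chi^2_d0 / d0` to
#' the observed per-analyte residual variances by working on the log scale
#' (digamma/trigamma moments, Newton inversion of the trigamma function).
#' When the observed spread of log-variances is no larger than the sampling
#' spread, `d0 = Inf` (complete pooling) is returned with a warning.
#'
#' @param sigma2 per-analyte residual variances.
#' @param df residual degrees of freedom (scalar or per-analyte).
#' @return list with `d0` (prior df) and `s0` (prior variance s0^2).
#' @export
fit_fdist <- function(sigma2, df) {
  if (length(df) == 1L) df <- rep(df, length(sigma2))
  ok <- sigma2 > 0 & is.finite(sigma2)
  if (sum(ok) < 10L)
    warning("fewer than 10 positive variances; hyperparameters are unstable")
  z <- log(sigma2[ok])
  e <- z - digamma(df[ok] / 2) + log(df[ok] / 2)
  emean <- mean(e)
  evar <- stats::var(e) * (sum(ok) - 1) / sum(ok) - mean(trigamma(df[ok] / 2))
  if (!is.finite(evar) || evar <= 0) {
    warning("log-variance spread below sampling noise; using d0 = Inf (complete pooling)")
    return(list(d0 = Inf, s0 = mean(sigma2[ok])))
  }
  d0 <- 2 * trigamma_inverse(evar)
  s0 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s0 = s0)
}

#' Moderated t-statistics via empirical-Bayes variance shrinkage
#'
#' Shrinks each analyte's residual variance towards the moment-matched
#' prior, `s2_post = (d0 s0^2 + df s^2) / (d0 + df)`, and tests the chosen
#' design coefficient with `t = beta / (stdev_unscaled * s_post)` on
#' `d0 + df` degrees of freedom.
#'
#' @param fit an `lm_fit` from [fit_linear_models()].
#' @param coef name or index of the design coefficient to test.
#' @return data.frame of class `de_table`: analyte_id, logFC, t, df_total,
#'   p, fdr, ordered as in the input matrix, with hyperparameters `d0`,
#'   `s0` in attributes.
#' @export
ebayes_moderate <- function(fit, coef) {
  stopifnot(inherits(fit, "lm_fit"))
  if (is.character(coef)) coef <- match(coef, colnames(fit$design))
  if (is.na(coef) || coef < 1 || coef > ncol(fit$design))
    stop("unknown design coefficient")
  hyper <- fit_fdist(fit$sigma2, fit$df)
  d0 <- hyper$d0; s0 <- hyper$s0
  s2_post <- if (is.finite(d0))
    (d0 * s0 + fit$df * fit$sigma2) / (d0 + fit$df)
  else rep(s0, length(fit$sigma2))
  beta <- fit$coefficients[coef, ]
  tt <- beta / (fit$stdev_unscaled[coef] * sqrt(s2_post))
  df_total <- min(d0 + fit$df, 1e6)
  p <- 2 * stats::pt(-abs(tt), df_total)
  out <- data.frame(analyte_id = colnames(fit$coefficients) %||%
                      as.character(seq_along(beta)),
                    logFC = beta, t = tt, df_total = df_total,
                    p = p, fdr = bh_fdr(p),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "d0") <- d0
  attr(out, "s0") <- s0
  attr(out, "s2_post") <- s2_post
  class(out) <- c("de_table", "data.frame")
  out
}

# moderated F test of a block of coefficients (full vs reduced design)
moderated_ftest <- function(values, design_full, design_reduced) {
  fit1 <- fit_linear_models(values, design_full)
  fit0 <- fit_linear_models(values, design_reduced)
  q <- ncol(fit1$design) - ncol(fit0$design)
  rss1 <- fit1$sigma2 * fit1$df
  rss0 <- fit0$sigma2 * fit0$df
  hyper <- fit_fdist(fit1$sigma2, fit1$df)
  d0 <- hyper$d0
  s2_post <- if (is.finite(d0))
    (d0 * hyper$s0 + fit1$df * fit1$sigma2) / (d0 + fit1$df)
  else rep(hyper$s0, length(fit1$sigma2))
  Fstat <- ((rss0 - rss1) / q) / s2_post
  df2 <- min(d0 + fit1$df, 1e6)
  p <- stats::pf(Fstat, q, df2, lower.tail = FALSE)
  data.frame(analyte_id = colnames(values) %||% as.character(seq_len(ncol(values))),
             F = Fstat, df1 = q, df2 = df2, p = p, fdr = bh_fdr(p),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Subcohort-stratified differential expression
#'
#' Runs the five standard comparisons: each subcohort's patients against
#' their own controls (GBA+, LRRK2+, idiopathic), all patients against all
#' controls (with mutation status and treatment as extra covariates), and
#' the disease-by-mutation interaction model. Each model adjusts for age,
#' sex, study centre and the supplied protein principal components; the
#' genetic-subcohort models additionally adjust for treatment (idiopathic
#' patients are drug-naive, so no treatment column there). The disease
#' coefficient is coded case = 1, so positive log2 fold changes mean higher
#' in patients. FDR is Benjamini-Hochberg within each comparison.
#' Comparisons with fewer than 3 cases or 3 controls are skipped (listed in
#' the `skipped` attribute).
#'
#' @param values samples x analytes matrix (batch-corrected log2 scale).
#' @param meta `sample_meta` with subcohort, status, age, sex, center,
#'   treated.
#' @param pcs samples x k matrix of protein principal components to adjust
#'   for (typically the first 4); `NULL` to omit.
#' @return named list of class `de_results` with one `de_table` per
#'   comparison (`gba`, `lrrk2`, `idiopathic`, `all`, `interaction`).
#' @export
run_comparisons <- function(values, meta, pcs = NULL) {
  check_matrix(values, "values")
  stopifnot(nrow(values) == nrow(meta))
  base_cov <- function(idx, treatment) {
    d <- data.frame(case = as.numeric(meta$status[idx] == "case"),
                    age = meta$age[idx],
                    sex = as.numeric(meta$sex[idx] == "M"))
    if (length(unique(meta$center[idx])) > 1L)
      d <- cbind(d, stats::model.matrix(~ center,
                                        data = data.frame(center = meta$center[idx]))[, -1, drop = FALSE])
    if (!is.null(pcs)) d <- cbind(d, pcs[idx, , drop = FALSE])
    if (treatment) d$treated <- as.numeric(meta$treated[idx])
    d
  }
  comparisons <- list(
    gba = list(idx = which(meta$subcohort == "GBA"), treatment = TRUE),
    lrrk2 = list(idx = which(meta$subcohort == "LRRK2"), treatment = TRUE),
    idiopathic = list(idx = which(meta$subcohort == "none"), treatment = FALSE),
    all = list(idx = seq_len(nrow(meta)), treatment = TRUE))
  out <- list()
  skipped <- character(0)
  for (nm in names(comparisons)) {
    idx <- comparisons[[nm]]$idx
    ncase <- sum(meta$status[idx] == "case")
    nctl <- sum(meta$status[idx] == "control")
    if (ncase < 3L || nctl < 3L) {
      skipped <- c(skipped, nm)
      next
    }
    cov <- base_cov(idx, comparisons[[nm]]$treatment)
    if (nm == "all")
      cov <- cbind(cov, stats::model.matrix(~ subcohort,
                                            data = data.frame(subcohort = meta$subcohort[idx]))[, -1, drop = FALSE])
    X <- stats::model.matrix(~ ., data = cov)
    fit <- fit_linear_models(values[idx, , drop = FALSE], X)
    tab <- ebayes_moderate(fit, "case")
    tab$comparison <- nm
    out[[nm]] <- tab
  }
  # interaction: disease x mutation status over the whole cohort
  cov <- base_cov(seq_len(nrow(meta)), TRUE)
  mut <- stats::model.matrix(~ subcohort,
                             data = data.frame(subcohort = meta$subcohort))[, -1, drop = FALSE]
  main <- cbind(cov, mut)
  inter <- cov$case * mut
  colnames(inter) <- paste0("case:", colnames(mut))
  X_full <- stats::model.matrix(~ ., data = cbind(main, inter))
  X_red <- stats::model.matrix(~ ., data = main)
  if (qr(X_full)$rank == ncol(X_full)) {
    tab <- moderated_ftest(values, X_full, X_red)
    tab$comparison <- "interaction"
    out$interaction <- tab
  } else skipped <- c(skipped, "interaction")
  attr(out, "skipped") <- skipped
  class(out) <- "de_results"
  out
}

#' @export
print.de_results <- function(x, ...) {
  cat("Differential expression results:\n")
  for (nm in names(x))
    cat(sprintf("  %-12s %5d analytes, %3d at FDR <= 0.05\n", nm,
                nrow(x[[nm]]), sum(x[[nm]]$fdr <= 0.05)))
  invisible(x)
}
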