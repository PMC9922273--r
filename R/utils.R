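#' Rank-based inverse normal transform
#'
#' Maps a numeric vector onto normal quantiles via its ranks,
#' `qnorm((r - offset) / (n - 2*offset + 1))`. The default offset 3/8 is the
#' Blom score, for which the transform of rank r among n values is
#' `qnorm((r - 3/8) / (n + 1/4))`. Ties receive the average rank, so any
#' strictly monotone transform of the input yields an identical output.
#'
#' @param x numeric vector, length >= 2, not constant.
#' @param offset rank offset c in `(r - c)/(n - 2c + 1)`; 3/8 by default.
#' @return numeric vector of normal scores, same length and names as `x`.
#' @export
inverse_normal_transform <- function(x, offset = 3/8) {
  if (length(x) < 2L) stop("inverse_normal_transform() needs at least 2 values")
  if (anyNA(x)) stop("inverse_normal_transform() does not accept missing values")
  if (diff(range(x)) == 0) stop("input is constant: all ranks tied, transform undefined")
  r <- rank(x, ties.method = "average")
  n <- length(x)
  out <- stats::qnorm((r - offset) / (n - 2 * offset + 1))
  names(out) <- names(x)
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment. Thin validated wrapper around
#' [stats::p.adjust()] so every stage of the pipeline shares one FDR entry
#' point.
#'
#' @param p vector of p-values in `[0, 1]`; NAs are propagated.
#' @return adjusted p-values, monotone in `p`, capped at 1.
#' @export
bh_fdr <- function(p) {
  pp <- p[!is.na(p)]
  if (length(pp) && (any(pp < 0) || any(pp > 1)))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

# log(sum(exp(x))) computed stably
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# AUC of scores against a binary truth via the rank (Mann-Whitney) identity
rank_auc <- function(scores, truth) {
  truth <- as.logical(truth)
  n1 <- sum(truth); n0 <- sum(!truth)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# shared validator: samples x features numeric matrix with dimnames
check_matrix <- function(m, what = "matrix") {
  if (!is.matrix(m) || !is.numeric(m))
    stop(sprintf("%s must be a numeric matrix", what))
  if (anyNA(m) || any(!is.finite(m)))
    stop(sprintf("%s contains non-finite values", what))
  invisible(m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
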