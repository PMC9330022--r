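# Basic sample-level QC: Pearson correlation heat-map input and PCA.

#' Sample-sample Pearson correlation matrix
#'
#' Pairs involving a constant (zero-variance) sample are undefined and
#' reported as NA.
#'
#' @param expr expression matrix, features x samples (>= 2 features).
#' @return symmetric samples x samples correlation matrix.
#' @export
qc_correlation <- function(expr) {
  if (nrow(expr) < 2) stop("need at least 2 features")
  sds <- apply(expr, 2, stats::sd)
  cc <- suppressWarnings(stats::cor(expr, method = "pearson"))
  cc[sds == 0, ] <- NA_real_
  cc[, sds == 0] <- NA_real_
  diag(cc)[sds > 0] <- 1
  cc
}

#' Principal component analysis of samples
#'
#' Features are centered, samples are projected by SVD. Variance fractions
#' are non-increasing and sum to at most 1.
#'
#' @param expr expression matrix, features x samples (>= 2 samples).
#' @param n_components number of components (at most samples - 1).
#' @return list with `scores` (samples x n_components) and `var_explained`
#'   (fraction of total variance per returned component).
#' @export
qc_pca <- function(expr, n_components = 2L) {
  n_samp <- ncol(expr)
  if (n_samp < 2) stop("need at least 2 samples")
  if (n_components > n_samp - 1)
    stop("n_components must be at most samples - 1")
  centered <- expr - rowMeans(expr)
  sv <- svd(t(centered))
  var_all <- sv$d^2 / sum(sv$d^2)
  scores <- sv$u %*% diag(sv$d, nrow = length(sv$d))
  rownames(scores) <- colnames(expr)
  list(scores = scores[, seq_len(n_components), drop = FALSE],
       var_explained = var_all[seq_len(n_components)])
}
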