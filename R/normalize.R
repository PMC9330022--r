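# TMM library normalization and counts-per-million.

#' Trimmed mean of M-values normalization factors
#'
#' Computes one scaling factor per sample against a reference sample, from
#' the weighted mean of log-ratios (M-values) after trimming 30% of M-values
#' and 5% of A-values at each tail; weights are the inverse asymptotic
#' binomial variances. Factors are rescaled to have geometric mean 1, so the
#' effective library size is `colSums(counts) * factors`.
#'
#' @param counts non-negative integer matrix, features x samples.
#' @param ref_sample reference sample id; default is the sample whose
#'   upper-quartile count fraction is closest to the across-sample mean.
#' @param logratio_trim,sum_trim tail trim fractions for M and A values.
#' @return object of class `norm_factors`: list with `factors` (named,
#'   geometric mean 1), `lib_sizes`, `ref_sample`.
#' @export
tmm_factors <- function(counts, ref_sample = NULL,
                        logratio_trim = 0.3, sum_trim = 0.05) {
  lib <- colSums(counts)
  if (any(lib == 0))
    stop("sample has all-zero counts: ",
         paste(colnames(counts)[lib == 0], collapse = ", "))
  f75 <- apply(counts, 2, stats::quantile, probs = 0.75) / lib
  if (is.null(ref_sample)) {
    ref_sample <- colnames(counts)[which.min(abs(f75 - mean(f75)))]
  } else if (!ref_sample %in% colnames(counts)) {
    stop("ref_sample not found: ", ref_sample)
  }
  refc <- counts[, ref_sample]
  n_ref <- lib[ref_sample]
  log2f <- vapply(colnames(counts), function(s) {
    if (s == ref_sample) return(0)
    obs <- counts[, s]
    n_obs <- lib[s]
    keep <- obs > 0 & refc > 0
    o <- obs[keep]; r <- refc[keep]
    if (!length(o)) return(0)
    M <- log2((o / n_obs) / (r / n_ref))
    A <- 0.5 * log2((o / n_obs) * (r / n_ref))
    w <- (n_obs - o) / (n_obs * o) + (n_ref - r) / (n_ref * r)
    n <- length(M)
    loM <- floor(n * logratio_trim) + 1; hiM <- n + 1 - loM
    loA <- floor(n * sum_trim) + 1;      hiA <- n + 1 - loA
    rM <- rank(M); rA <- rank(A)
    use <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
    if (!any(use)) return(0)
    f <- sum(w[use] * M[use]) / sum(w[use])
    if (!is.finite(f)) 0 else f
  }, numeric(1))
  factors <- 2^log2f
  factors <- factors / exp(mean(log(factors)))
  structure(list(factors = factors, lib_sizes = lib, ref_sample = ref_sample),
            class = "norm_factors")
}

effective_lib_sizes <- function(norm) {
  norm$lib_sizes * norm$factors
}

#' Counts per million
#'
#' Scales counts to per-million rates using TMM effective library sizes. The
#' log variant computes `log2((count + prior_j) / (eff_lib_j + 2 prior_j) *
#' 1e6)` with the prior count scaled proportionally to each sample's
#' effective library size, which stabilizes zeros without biasing
#' between-sample ratios.
#'
#' @param counts features x samples matrix.
#' @param norm a [tmm_factors()] result on the same samples.
#' @param log logical; return log2-CPM.
#' @param prior_count average prior count added in the log variant.
#' @return numeric matrix of (log2-)CPM values.
#' @export
cpm_matrix <- function(counts, norm, log = FALSE, prior_count = 2) {
  if (!identical(sort(colnames(counts)), sort(names(norm$factors))))
    stop("norm factors were computed on a different sample set")
  eff <- effective_lib_sizes(norm)[colnames(counts)]
  if (!log)
    return(sweep(counts, 2, eff, "/") * 1e6)
  pc <- prior_count * eff / mean(eff)
  num <- sweep(counts, 2, pc, "+")
  den <- eff + 2 * pc
  log2(sweep(num, 2, den, "/") * 1e6)
}
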