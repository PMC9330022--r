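# Common-dispersion NB exact test for two-group comparisons, thresholds and
# DE calls.

#' Differential-expression thresholds for small-RNA (DEM) calls
#'
#' Defaults follow the conventional small-replicate screen: absolute log2
#' fold change at least 1.5, average log2-CPM strictly above 2, and BH FDR
#' at most 0.05.
#'
#' @param min_abs_log2fc minimum |log2FC| (inclusive).
#' @param min_log2cpm minimum average log2CPM (exclusive).
#' @param max_fdr maximum BH-adjusted p (inclusive).
#' @return list of class `de_thresholds`.
#' @export
de_thresholds <- function(min_abs_log2fc = 1.5, min_log2cpm = 2,
                          max_fdr = 0.05) {
  stopifnot(min_abs_log2fc > 0, max_fdr > 0, max_fdr <= 1)
  structure(list(min_abs_log2fc = min_abs_log2fc, min_log2cpm = min_log2cpm,
                 max_fdr = max_fdr), class = "de_thresholds")
}

#' Thresholds for the gene-level (DEG) t-test screen
#'
#' @param min_fc minimum linear fold change (DE if FC >= min_fc or
#'   <= 1/min_fc).
#' @param alpha familywise level for the Bonferroni-adjusted Welch t-test.
#' @return list of class `deg_thresholds`.
#' @export
deg_thresholds <- function(min_fc = 2, alpha = 0.05) {
  stopifnot(min_fc > 1, alpha > 0, alpha <= 1)
  structure(list(min_fc = min_fc, alpha = alpha), class = "deg_thresholds")
}

# Conditional distribution of the group-A pseudo-sum given the total, under
# NB with common dispersion: the "negative hypergeometric" weights
# w(k) = C(k + ra - 1, k) C(t - k + rb - 1, t - k), normalized. phi = 0 is
# the Poisson limit, a plain binomial split.
split_distribution <- function(total, n_a, n_b, phi) {
  k <- 0:total
  if (phi == 0)
    return(stats::dbinom(k, total, n_a / (n_a + n_b)))
  ra <- n_a / phi; rb <- n_b / phi
  lw <- lgamma(k + ra) - lgamma(k + 1) - lgamma(ra) +
    lgamma(total - k + rb) - lgamma(total - k + 1) - lgamma(rb)
  w <- exp(lw - max(lw))
  w / sum(w)
}

# Two-sided p by doubling the smaller conditional tail, capped at 1.
exact_split_pvalue <- function(s_a, total, n_a, n_b, phi) {
  if (total == 0) return(1)
  pr <- split_distribution(total, n_a, n_b, phi)
  lower <- sum(pr[seq_len(s_a + 1)])
  upper <- sum(pr[(s_a + 1):(total + 1)])
  min(1, 2 * min(lower, upper))
}

#' Exact NB test for a two-group comparison
#'
#' Counts are quantile-adjusted to a common effective library size
#' (pseudo-counts). Per feature, the conditional distribution of the group-A
#' pseudo-sum given the feature total is enumerated under a common-dispersion
#' negative binomial, and the two-sided p-value doubles the smaller tail
#' (capped at 1). log2FC is computed from per-sample normalized group means
#' with a prior count of 0.125; logCPM from the mean pseudo-count with a
#' prior of 2.
#'
#' @param counts features x samples count matrix containing both groups.
#' @param group_a,group_b disjoint character vectors of sample ids.
#' @param phi common NB dispersion (>= 0).
#' @param norm optional [tmm_factors()] result covering both groups;
#'   computed on the two groups' columns if missing.
#' @param comparison label stored on the result (default "A-B").
#' @return data.frame with `feature`, `logFC` (A over B), `logCPM`,
#'   `pvalue`; the comparison label is kept in attribute `"comparison"`.
#' @export
nb_exact_test <- function(counts, group_a, group_b, phi, norm = NULL,
                          comparison = "A-B") {
  if (phi < 0) stop("dispersion must be non-negative")
  if (length(intersect(group_a, group_b)))
    stop("groups must be disjoint")
  if (!length(group_a) || !length(group_b))
    stop("both groups must be non-empty")
  stopifnot(all(c(group_a, group_b) %in% colnames(counts)))
  sub <- counts[, c(group_a, group_b), drop = FALSE]
  if (is.null(norm)) norm <- tmm_factors(sub)
  eff <- effective_lib_sizes(norm)[colnames(sub)]
  grp <- factor(rep(c("A", "B"), c(length(group_a), length(group_b))))
  ps <- pseudo_counts(sub, eff, grp, phi)
  pseudo <- ps$pseudo
  n_a <- length(group_a); n_b <- length(group_b)
  s_a <- rowSums(pseudo[, seq_len(n_a), drop = FALSE])
  s_b <- rowSums(pseudo[, n_a + seq_len(n_b), drop = FALSE])
  sa_r <- round(s_a); sb_r <- round(s_b)
  pvalue <- vapply(seq_len(nrow(sub)), function(i) {
    exact_split_pvalue(sa_r[i], sa_r[i] + sb_r[i], n_a, n_b, phi)
  }, numeric(1))
  prior <- 0.125
  logFC <- log2((s_a / n_a + prior) / (s_b / n_b + prior))
  logCPM <- log2((rowMeans(pseudo) + 2) / ps$common_lib * 1e6)
  out <- data.frame(feature = rownames(sub), logFC = logFC, logCPM = logCPM,
                    pvalue = pvalue, row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "comparison") <- comparison
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH with cumulative-minimum enforcement, preserving input order.
#'
#' @param pvalues numeric vector in [0, 1].
#' @return adjusted values in input order.
#' @export
bh_adjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Call differentially expressed features (DEMs) for one comparison
#'
#' Adds BH FDR to a [nb_exact_test()] result and flags features meeting all
#' three thresholds: |log2FC| >= min, logCPM strictly > min, FDR <= max.
#' Direction is `UP_IN_A` for positive log2FC, `UP_IN_B` for negative,
#' `NONE` for non-DE features.
#'
#' @param result data.frame from [nb_exact_test()].
#' @param thresholds a [de_thresholds()] object.
#' @return the result with `fdr`, `de`, `direction` columns.
#' @export
call_dems <- function(result, thresholds = de_thresholds()) {
  stopifnot(inherits(thresholds, "de_thresholds"),
            all(c("feature", "logFC", "logCPM", "pvalue") %in% names(result)))
  result$fdr <- bh_adjust(result$pvalue)
  result$de <- abs(result$logFC) >= thresholds$min_abs_log2fc &
    result$logCPM > thresholds$min_log2cpm &
    result$fdr <= thresholds$max_fdr
  result$direction <- ifelse(!result$de, "NONE",
                             ifelse(result$logFC > 0, "UP_IN_A", "UP_IN_B"))
  result
}

#' Welch t-test screen for differentially expressed genes (DEGs)
#'
#' Row-wise Welch two-sample t-tests with Bonferroni adjustment; a gene is
#' DE when the adjusted p is at or below `alpha` and the linear fold change
#' is at least `min_fc` (or at most its reciprocal).
#'
#' @param expr expression matrix (linear scale), genes x samples.
#' @param group_a,group_b sample id vectors, each of size >= 2.
#' @param thresholds a [deg_thresholds()] object.
#' @return data.frame with `feature`, `fc` (A over B), `pvalue`, `p_adj`,
#'   `de`.
#' @export
deg_ttest <- function(expr, group_a, group_b, thresholds = deg_thresholds()) {
  stopifnot(inherits(thresholds, "deg_thresholds"))
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("each group needs at least 2 replicates")
  a <- expr[, group_a, drop = FALSE]
  b <- expr[, group_b, drop = FALSE]
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- apply(a, 1, stats::var); vb <- apply(b, 1, stats::var)
  se2 <- va / na + vb / nb
  tstat <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  # degenerate zero-variance rows: identical groups are null, separated
  # groups are certain
  p[se2 == 0 & ma == mb] <- 1
  p[se2 == 0 & ma != mb] <- 0
  p_adj <- stats::p.adjust(p, method = "bonferroni")
  fc <- ma / mb
  de <- p_adj <= thresholds$alpha &
    (fc >= thresholds$min_fc | fc <= 1 / thresholds$min_fc)
  data.frame(feature = rownames(expr), fc = fc, pvalue = p, p_adj = p_adj,
             de = de, row.names = NULL, stringsAsFactors = FALSE)
}
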