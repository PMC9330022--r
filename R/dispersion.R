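# Common NB dispersion by conditional maximum likelihood on
# quantile-adjusted (equal-library) pseudo-counts.

# Map counts observed at mean `input_mean` to the quantile-equivalent value
# at `output_mean` under NB(dispersion), averaging the normal and gamma
# continuous approximations of the NB cdf. This is the standard construction
# for equalizing library sizes before a conditional-likelihood analysis.
q2q_nbinom <- function(x, input_mean, output_mean, dispersion) {
  zero <- input_mean < 1e-14 | output_mean < 1e-14
  input_mean[zero] <- input_mean[zero] + 0.25
  output_mean[zero] <- output_mean[zero] + 0.25
  ri <- 1 + dispersion * input_mean
  vi <- input_mean * ri
  ro <- 1 + dispersion * output_mean
  vo <- output_mean * ro
  q <- x
  up <- x >= input_mean
  if (any(up)) {
    p1 <- stats::pnorm(x[up], input_mean[up], sqrt(vi[up]), lower.tail = FALSE)
    p2 <- stats::pgamma(x[up], shape = input_mean[up]^2 / vi[up],
                        scale = vi[up] / input_mean[up], lower.tail = FALSE)
    q1 <- stats::qnorm(p1, output_mean[up], sqrt(vo[up]), lower.tail = FALSE)
    q2 <- stats::qgamma(p2, shape = output_mean[up]^2 / vo[up],
                        scale = vo[up] / output_mean[up], lower.tail = FALSE)
    q[up] <- (q1 + q2) / 2
  }
  dn <- !up
  if (any(dn)) {
    p1 <- stats::pnorm(x[dn], input_mean[dn], sqrt(vi[dn]), lower.tail = TRUE)
    p2 <- stats::pgamma(x[dn], shape = input_mean[dn]^2 / vi[dn],
                        scale = vi[dn] / input_mean[dn], lower.tail = TRUE)
    q1 <- stats::qnorm(p1, output_mean[dn], sqrt(vo[dn]), lower.tail = TRUE)
    q2 <- stats::qgamma(p2, shape = output_mean[dn]^2 / vo[dn],
                        scale = vo[dn] / output_mean[dn], lower.tail = TRUE)
    q[dn] <- (q1 + q2) / 2
  }
  pmax(q, 0)
}

# Pseudo-counts at a common library size for a set of samples assumed to
# share one mean rate per feature (per group). `groups` is a factor over
# columns; rates are estimated within group so planted differences do not
# leak into the adjustment.
pseudo_counts <- function(counts, eff_lib, groups, dispersion) {
  common <- exp(mean(log(eff_lib)))
  pseudo <- counts * 0
  for (g in levels(groups)) {
    idx <- which(groups == g)
    lam <- rowSums(counts[, idx, drop = FALSE]) / sum(eff_lib[idx])
    for (j in idx) {
      pseudo[, j] <- q2q_nbinom(counts[, j], lam * eff_lib[j],
                                lam * common, dispersion)
    }
  }
  list(pseudo = pseudo, common_lib = common)
}

# Conditional NB log-likelihood of a common dispersion given equal-library
# pseudo-counts, summed over features and groups (groups with < 2 replicates
# carry no information and are skipped).
cond_loglik <- function(pseudo, groups, phi) {
  r <- 1 / phi
  ll <- 0
  for (g in levels(groups)) {
    idx <- which(groups == g)
    n <- length(idx)
    if (n < 2) next
    y <- pseudo[, idx, drop = FALSE]
    z <- rowSums(y)
    ll <- ll + sum(rowSums(lgamma(y + r)) + lgamma(n * r) -
                     lgamma(z + n * r) - n * lgamma(r))
  }
  ll
}

#' Estimate a common NB dispersion by conditional maximum likelihood
#'
#' Counts are quantile-adjusted to a common (geometric-mean) effective
#' library size, then the conditional likelihood of the dispersion given the
#' per-group feature totals is maximized over a log-spaced grid followed by
#' `optimize()` refinement in the bracketing interval. Groups with fewer
#' than two replicates contribute nothing; if no group has replication the
#' estimate is 0 with a warning.
#'
#' @param counts features x samples count matrix.
#' @param groups factor (or coercible) of group membership per sample.
#' @param norm optional [tmm_factors()] result; computed if missing.
#' @return non-negative dispersion estimate (phi, variance = mu + phi mu^2).
#' @export
estimate_common_dispersion <- function(counts, groups, norm = NULL) {
  groups <- droplevels(as.factor(groups))
  stopifnot(length(groups) == ncol(counts))
  if (!any(table(groups) >= 2)) {
    warning("no group has >= 2 replicates; returning dispersion 0")
    return(0)
  }
  if (is.null(norm)) norm <- tmm_factors(counts)
  eff <- effective_lib_sizes(norm)[colnames(counts)]
  grid <- 10^seq(-4, 1, length.out = 25)
  ll <- vapply(grid, function(phi) {
    ps <- pseudo_counts(counts, eff, groups, phi)$pseudo
    cond_loglik(ps, groups, phi)
  }, numeric(1))
  i <- which.max(ll)
  lo <- grid[max(1, i - 1)]
  hi <- grid[min(length(grid), i + 1)]
  opt <- stats::optimize(function(phi) {
    ps <- pseudo_counts(counts, eff, groups, phi)$pseudo
    cond_loglik(ps, groups, phi)
  }, lower = lo, upper = hi, maximum = TRUE, tol = 1e-5)
  phi <- opt$maximum
  # prefer the boundary when the grid maximum sits at the smallest phi
  if (i == 1 && ll[1] >= opt$objective) phi <- grid[1]
  if (phi <= 1.5e-4) phi <- 0
  phi
}
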