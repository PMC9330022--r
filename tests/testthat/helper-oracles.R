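# Independent brute-force / closed-form oracles used across the suite.
# These deliberately take different computational routes from the package
# implementations.

# Trimmed weighted mean of M-values for one sample against a reference,
# computed by explicit sorting (no rank bookkeeping). Returns the log2
# scaling factor.
oracle_tmm_log2 <- function(obs, ref, logratio_trim = 0.3, sum_trim = 0.05) {
  n_obs <- sum(obs); n_ref <- sum(ref)
  keep <- obs > 0 & ref > 0
  o <- obs[keep]; r <- ref[keep]
  M <- log2((o / n_obs) / (r / n_ref))
  A <- 0.5 * log2((o / n_obs) * (r / n_ref))
  w <- (n_obs - o) / (n_obs * o) + (n_ref - r) / (n_ref * r)
  n <- length(M)
  keepM <- order(M)[(floor(n * logratio_trim) + 1):(n - floor(n * logratio_trim))]
  keepA <- order(A)[(floor(n * sum_trim) + 1):(n - floor(n * sum_trim))]
  use <- intersect(keepM, keepA)
  sum(w[use] * M[use]) / sum(w[use])
}

# Conditional probability mass of the group-A sum given the total, by
# normalizing products of NB densities (dnbinom route, distinct from the
# implementation's lgamma-weight route).
oracle_split_pmf <- function(total, n_a, n_b, phi) {
  k <- 0:total
  mu_a <- pmax(total, 1) * n_a / (n_a + n_b)
  mu_b <- pmax(total, 1) * n_b / (n_a + n_b)
  w <- stats::dnbinom(k, size = n_a / phi, mu = mu_a) *
    stats::dnbinom(total - k, size = n_b / phi, mu = mu_b)
  w / sum(w)
}

oracle_split_pvalue <- function(s_a, total, n_a, n_b, phi) {
  pr <- oracle_split_pmf(total, n_a, n_b, phi)
  lower <- sum(pr[1:(s_a + 1)])
  upper <- sum(pr[(s_a + 1):(total + 1)])
  min(1, 2 * min(lower, upper))
}

# Closed-form balanced two-way ANOVA from cell means.
oracle_anova <- function(values, breed, env) {
  breed <- factor(breed); env <- factor(env)
  n <- table(breed, env)[1, 1]
  grand <- mean(values)
  mb <- tapply(values, breed, mean)
  me <- tapply(values, env, mean)
  cells <- tapply(values, list(breed, env), mean)
  ss_breed <- 2 * n * sum((mb - grand)^2)
  ss_env <- 2 * n * sum((me - grand)^2)
  ss_int <- n * sum((outer(mb - grand, me - grand, "+") + grand - cells)^2)
  fitted <- cells[cbind(as.character(breed), as.character(env))]
  ss_resid <- sum((values - fitted)^2)
  df_res <- length(values) - 4
  list(ss = c(ss_breed, ss_env, ss_int, ss_resid),
       f = c(ss_breed, ss_env, ss_int) / (ss_resid / df_res),
       p = stats::pf(c(ss_breed, ss_env, ss_int) / (ss_resid / df_res),
                     1, df_res, lower.tail = FALSE))
}

# Average pairwise difference per site among the 2n sampled alleles,
# enumerated pair by pair.
oracle_pi_pairwise_mat <- function(geno, window_length) {
  # geno: sites x individuals dosage matrix
  tot <- 0
  for (s in seq_len(nrow(geno))) {
    al <- unlist(lapply(geno[s, ], function(d) c(rep(1L, d), rep(0L, 2L - d))))
    m <- length(al)
    diffs <- 0
    for (i in seq_len(m - 1))
      for (j in (i + 1):m)
        diffs <- diffs + (al[i] != al[j])
    tot <- tot + diffs / choose(m, 2)
  }
  tot / window_length
}

# Interval union by marking covered positions (small coordinates only).
oracle_merge <- function(starts, ends) {
  covered <- rep(FALSE, max(ends))
  for (i in seq_along(starts)) covered[starts[i]:ends[i]] <- TRUE
  r <- rle(covered)
  cum <- cumsum(r$lengths)
  begin <- c(1, head(cum, -1) + 1)
  data.frame(start = begin[r$values], end = cum[r$values])
}

# Quadratic all-pairs overlap of 1-based inclusive intervals.
oracle_overlaps <- function(regions, genes) {
  hits <- list()
  for (i in seq_len(nrow(regions))) {
    ids <- character(0)
    for (j in seq_len(nrow(genes))) {
      if (regions$chrom[i] == genes$chrom[j] &&
          regions$start[i] <= genes$end[j] &&
          regions$end[i] >= genes$start[j])
        ids <- c(ids, genes$gene_id[j])
    }
    hits[[i]] <- sort(unique(ids))
  }
  hits
}
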