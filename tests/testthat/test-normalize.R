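test_that("identical libraries get unit factors and the geometric mean is 1", {
  set.seed(4)
  x <- matrix(rpois(200, 50), 100, 2, dimnames = list(NULL, c("a", "b")))
  x[, 2] <- x[, 1]
  nf <- tmm_factors(x)
  expect_equal(unname(nf$factors), c(1, 1))

  y <- matrix(rpois(500, 30), 100, 5,
              dimnames = list(NULL, paste0("s", 1:5)))
  nf2 <- tmm_factors(y)
  expect_equal(exp(mean(log(nf2$factors))), 1, tolerance = 1e-8)
})

test_that("all-zero samples are rejected by name", {
  x <- matrix(c(1:10, rep(0, 10)), 10, 2,
              dimnames = list(NULL, c("ok", "empty")))
  expect_error(tmm_factors(x), "empty")
})

test_that("a scaled library with spiked features matches the hand-scripted trimmed-mean oracle", {
  set.seed(7)
  base <- rpois(20, 100) + 1
  obs <- rpois(20, 3 * base) + 1L
  obs[1:2] <- obs[1:2] * 20L  # spiked features that trimming should drop
  x <- cbind(ref = base, obs = obs)
  rownames(x) <- paste0("f", 1:20)
  nf <- tmm_factors(x, ref_sample = "ref")
  log2f <- oracle_tmm_log2(obs, base)
  expected <- 2^c(0, log2f)
  expected <- expected / exp(mean(log(expected)))
  expect_equal(unname(nf$factors), unname(expected), tolerance = 1e-10)
})

test_that("factors agree with an independent TMM implementation on simulated data", {
  skip_if_not_installed("edgeR")
  p <- count_sim_params(n_features = 500, frac_en = 0.05, frac_br = 0,
                        frac_int = 0, seed = 23)
  sim <- simulate_counts(p)
  mine <- tmm_factors(sim$counts)$factors
  theirs <- edgeR::calcNormFactors(sim$counts, method = "TMM")
  expect_equal(unname(mine), unname(theirs), tolerance = 0.02)
})

test_that("effective library sizes recover planted library sizes within 5%", {
  p <- count_sim_params(n_features = 1000, frac_en = 0.05, frac_br = 0.02,
                        frac_int = 0.02, lib_size_range = c(5e5, 2e6),
                        seed = 41)
  sim <- simulate_counts(p)
  nf <- tmm_factors(sim$counts)
  eff <- nf$lib_sizes * nf$factors
  ratio <- eff / sim$truth$lib_sizes[names(eff)]
  ratio <- ratio / exp(mean(log(ratio)))  # overall scale is arbitrary
  expect_lt(max(abs(ratio - 1)), 0.05)
})

test_that("cpm obeys its arithmetic contracts", {
  x <- matrix(c(100L, 0L, 0L, 0L, 50L, 50L), 3, 2,
              dimnames = list(paste0("f", 1:3), c("a", "b")))
  nf <- structure(list(factors = c(a = 1, b = 1),
                       lib_sizes = colSums(x), ref_sample = "a"),
                  class = "norm_factors")
  cp <- cpm_matrix(x, nf)
  # a single feature holding an entire library maps to 1e6; zeros stay 0
  expect_equal(cp["f1", "a"], 1e6)
  expect_equal(cp["f2", "a"], 0)
  # hand-computed count / libsize * 1e6 under unit factors
  expect_equal(unname(cp[, "b"]), c(0, 50, 50) / 100 * 1e6)
  # log variant: documented prior formula
  lcp <- cpm_matrix(x, nf, log = TRUE, prior_count = 2)
  expect_equal(lcp["f2", "b"], log2((50 + 2) / (100 + 4) * 1e6))
  # mismatched sample sets are refused
  expect_error(cpm_matrix(x[, 1, drop = FALSE], nf), "different sample set")
})
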