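test_that("a perfectly symmetric comparison gives logFC 0 and p 1", {
  x <- matrix(rep(c(10L, 40L, 0L, 100L), 2), 4, 2,
              dimnames = list(paste0("f", 1:4), c("a", "b")))
  res <- nb_exact_test(x, "a", "b", phi = 0.1)
  expect_equal(res$logFC, rep(0, 4))
  expect_equal(res$pvalue, rep(1, 4))
})

test_that("the Poisson limit reproduces the exact binomial test", {
  # 1v1, equal library sizes, phi = 0: the conditional split distribution is
  # Binomial(total, 1/2); agreement with binom.test to 1e-10 for all totals
  for (total in 1:50) {
    for (s_a in c(0L, total %/% 3L, total)) {
      mine <- plastisweep:::exact_split_pvalue(s_a, total, 1, 1, 0)
      expect_equal(mine, binom.test(s_a, total, 0.5)$p.value,
                   tolerance = 1e-10)
    }
  }
})

test_that("small NB splits match brute-force enumeration", {
  for (phi in c(0.05, 0.1, 0.5)) {
    for (total in c(5L, 10L, 23L)) {
      for (s_a in 0:total) {
        expect_equal(plastisweep:::exact_split_pvalue(s_a, total, 2, 2, phi),
                     oracle_split_pvalue(s_a, total, 2, 2, phi),
                     tolerance = 1e-10)
      }
    }
  }
  # unbalanced group sizes too
  expect_equal(plastisweep:::exact_split_pvalue(7L, 10L, 2, 3, 0.1),
               oracle_split_pvalue(7L, 10L, 2, 3, 0.1), tolerance = 1e-10)
})

test_that("nb_exact_test validates its inputs", {
  x <- matrix(1:8, 4, 2, dimnames = list(paste0("f", 1:4), c("a", "b")))
  expect_error(nb_exact_test(x, "a", "b", phi = -1), "non-negative")
  expect_error(nb_exact_test(x, "a", "a", phi = 0.1), "disjoint")
  expect_error(nb_exact_test(x, character(0), "b", phi = 0.1), "non-empty")
})

test_that("BH adjustment matches hand computation and preserves order", {
  expect_equal(bh_adjust(0.05), 0.05)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(13)
  p <- runif(50)
  perm <- sample(50)
  expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("DEM thresholds use the stated boundary semantics", {
  mk <- function(logFC, logCPM, p) {
    r <- data.frame(feature = "f1", logFC = logFC, logCPM = logCPM,
                    pvalue = p)
    call_dems(r)$de
  }
  # logCPM must be strictly greater than 2
  expect_false(mk(1.5, 2.0, 0.05))
  # |logFC| >= 1.5 and FDR <= 0.05 are inclusive
  expect_true(mk(1.5, 2.1, 0.05))
  expect_true(mk(-1.5, 2.1, 0.05))
  expect_false(mk(1.49, 2.1, 0.05))
  # empty results stay empty
  empty <- data.frame(feature = character(), logFC = numeric(),
                      logCPM = numeric(), pvalue = numeric())
  expect_equal(nrow(call_dems(empty)), 0)
})

test_that("direction labels follow the sign of the fold change", {
  r <- data.frame(feature = c("up", "down", "flat"),
                  logFC = c(3, -3, 0.1), logCPM = c(5, 5, 5),
                  pvalue = c(1e-6, 1e-6, 0.9))
  out <- call_dems(r)
  expect_equal(out$direction, c("UP_IN_A", "UP_IN_B", "NONE"))
})

test_that("deg_ttest matches t.test per gene and applies both filters", {
  set.seed(77)
  expr <- matrix(rlnorm(60, 4, 0.3), 10, 6,
                 dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
  expr[1, 1:3] <- expr[1, 1:3] * 20  # large separation
  ga <- paste0("s", 1:3); gb <- paste0("s", 4:6)
  res <- deg_ttest(expr, ga, gb)
  for (g in rownames(expr)) {
    ref <- t.test(expr[g, ga], expr[g, gb])$p.value
    expect_equal(res$pvalue[res$feature == g], ref, tolerance = 1e-10)
  }
  # identical groups yield no calls
  same <- expr[, c(1:3, 1:3)]
  colnames(same) <- paste0("s", 1:6)
  expect_equal(sum(deg_ttest(same, ga, gb)$de), 0)
  # zero-variance separated gene is certain
  sep <- matrix(c(8, 8, 8, 1, 1, 1), 1, 6,
                dimnames = list("g", paste0("s", 1:6)))
  out <- deg_ttest(sep, ga, gb)
  expect_true(out$de)
  expect_equal(out$p_adj, 0)
  expect_equal(out$fc, 8)
  expect_error(deg_ttest(expr, "s1", gb), "2 replicates")
})
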