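test_that("site-level components behave at the boundaries", {
  # equal frequencies, equal sizes, HWE heterozygosity: estimate <= 0
  n <- 50; p <- 0.3
  het <- round(2 * p * (1 - p) * n)
  ac <- round(2 * n * p)
  cmp <- site_fst_components(n, ac, het, n, ac, het)
  expect_lte(cmp$a / cmp$d, 0)
  # fixed difference with large equal n approaches 1
  big <- 5000
  cmp2 <- site_fst_components(big, 2 * big, 0, big, 0, 0)
  expect_gt(cmp2$a / cmp2$d, 1 - 1 / big * 5)
  # monomorphic across both populations: components (0, 0)
  mono <- site_fst_components(10, 0, 0, 10, 0, 0)
  expect_equal(unlist(mono), c(a = 0, d = 0))
  # too few called genotypes: NA
  none <- site_fst_components(0, 0, 0, 10, 5, 3)
  expect_true(is.na(none$a))
})

test_that("the toy site matches the variance-components oracle values", {
  # 10 diploids per population, alt counts 15 vs 5, het counts 5 vs 3;
  # expected values frozen from an independent implementation of the
  # Weir-Cockerham components
  cmp <- site_fst_components(10, 15, 5, 10, 5, 3)
  expect_equal(cmp$a, 0.1152777777777778, tolerance = 1e-10)
  expect_equal(cmp$d, 0.3125, tolerance = 1e-10)
  expect_equal(cmp$a / cmp$d, 0.3688888888888889, tolerance = 1e-10)
})

test_that("window Fst reduces, skips and clamps correctly", {
  one <- site_fst_components(10, 15, 5, 10, 5, 3)
  expect_equal(window_fst(one), one$a / one$d)
  mono <- site_fst_components(c(10, 10), c(0, 20), c(0, 0),
                              c(10, 10), c(0, 20), c(0, 0))
  expect_true(is.na(window_fst(mono)))
  # ratio of sums, not mean of ratios
  two <- site_fst_components(c(10, 10), c(15, 8), c(5, 6), c(10, 10),
                             c(5, 12), c(3, 8))
  expect_equal(window_fst(two, clamp = FALSE),
               sum(two$a) / sum(two$d), tolerance = 1e-12)
})

test_that("window pi matches the closed form and the pairwise oracle", {
  # one site, sample frequency 0.5, 10 diploids
  expect_equal(window_pi(10, 10, 1) , 2 * 0.25 * 20 / 19, tolerance = 1e-12)
  expect_equal(window_pi(10, 10, 40000) * 40000, 0.5263158,
               tolerance = 1e-6)
  # 4-haplotype (2-diploid) toy, several sites, vs direct pair enumeration
  geno <- rbind(c(1L, 0L), c(2L, 1L), c(0L, 1L), c(2L, 2L), c(1L, 1L))
  n <- rep(2, nrow(geno)); ac <- rowSums(geno)
  expect_equal(window_pi(n, ac, 100),
               oracle_pi_pairwise_mat(geno, 100), tolerance = 1e-10)
  # monomorphic window
  expect_equal(window_pi(10, 0, 100), 0)
})

test_that("sliding windows tile chromosomes as specified", {
  w <- make_windows(c(chr1 = 100000), window = 40000, step = 20000)
  expect_equal(w$start, c(1, 20001, 40001, 60001, 80001))
  expect_equal(w$end, w$start + 39999)
  expect_equal(w$partial, c(FALSE, FALSE, FALSE, FALSE, TRUE))
  # window = step gives a non-overlapping tiling covering the chromosome
  t1 <- make_windows(c(chr1 = 95000), window = 20000, step = 20000)
  expect_true(all(t1$start[-1] == head(t1$end, -1) + 1))
  expect_gte(sum(t1$end - t1$start + 1), 95000)
  expect_error(make_windows(c(chr1 = 1e5), window = 100, step = 200))
})

test_that("region calling merges overlapping windows like an interval union", {
  win <- data.frame(chrom = "c1",
                    start = c(1, 20001, 80001, 120001),
                    end = c(40000, 60000, 120000, 160000),
                    partial = FALSE,
                    fst = c(0.5, 0.4, 0.35, 0.1))
  reg <- call_regions(win, fst_threshold = 0.3)
  expect_equal(reg$start, c(1, 80001))
  expect_equal(reg$end, c(60000, 120000))
  expect_equal(reg$peak_fst, c(0.5, 0.35))
  expect_equal(nrow(call_regions(win, fst_threshold = 0.9)), 0)

  # random qualifying patterns against the brute-force union oracle
  set.seed(14)
  for (rep in 1:5) {
    starts <- seq(1, 181, by = 20)
    qual <- data.frame(chrom = "c1", start = starts, end = starts + 39,
                       partial = FALSE, fst = runif(10))
    reg <- call_regions(qual, fst_threshold = 0.5)
    keep <- qual[qual$fst >= 0.5, ]
    if (nrow(keep)) {
      orc <- oracle_merge(keep$start, keep$end)
      expect_equal(reg$start, orc$start)
      expect_equal(reg$end, orc$end)
    } else {
      expect_equal(nrow(reg), 0)
    }
  }
})

test_that("partial windows are excluded from region calling by default", {
  win <- data.frame(chrom = "c1", start = c(1, 20001), end = c(40000, 60000),
                    partial = c(FALSE, TRUE), fst = c(0.5, 0.9))
  expect_equal(call_regions(win)$end, 40000)
  expect_equal(call_regions(win, include_partial = TRUE)$end, 60000)
})

test_that("gene annotation overlaps by at least one base and deduplicates", {
  regions <- data.frame(chrom = "c1", start = c(1, 100), end = c(50, 150),
                        n_windows = 1L, peak_fst = 0.5)
  genes <- data.frame(chrom = "c1", start = c(51, 40, 1),
                      end = c(60, 120, 200),
                      gene_id = c("abut", "span", "cover"))
  ann <- annotate_regions(regions, genes)
  expect_equal(ann$genes, c("cover,span", "cover,span"))
  expect_false(grepl("abut", paste(ann$genes, collapse = "")))
  expect_equal(attr(ann, "n_genes"), 2)

  # random toys against the quadratic all-pairs oracle
  set.seed(15)
  for (rep in 1:5) {
    r <- data.frame(chrom = sample(c("c1", "c2"), 6, TRUE),
                    start = sample(1:500, 6), n_windows = 1L, peak_fst = 0.4)
    r$end <- r$start + sample(10:100, 6)
    g <- data.frame(chrom = sample(c("c1", "c2"), 8, TRUE),
                    start = sample(1:500, 8), gene_id = paste0("g", 1:8))
    g$end <- g$start + sample(5:80, 8)
    ann <- annotate_regions(r, g)
    orc <- oracle_overlaps(r, g)
    for (i in seq_len(nrow(r))) {
      got <- if (nzchar(ann$genes[i]))
        strsplit(ann$genes[i], ",")[[1]] else character(0)
      expect_setequal(got, orc[[i]])
    }
  }
})

test_that("BED annotation read through the importer uses 1-based inclusive coordinates", {
  genes <- data.frame(chrom = "chrSim", start = c(101, 500),
                      end = c(200, 700), gene_id = c("gA", "gB"))
  bed <- withr::local_tempfile(fileext = ".bed")
  write_bed(genes, bed)
  regions <- data.frame(chrom = "chrSim", start = 150, end = 480,
                        n_windows = 1L, peak_fst = 0.4)
  ann <- annotate_regions(regions, bed)
  expect_equal(ann$genes, "gA")
  expect_error(annotate_regions(regions, "genes.xls"), "unknown annotation")
})

test_that("population relabelling swaps pi and leaves Fst unchanged", {
  p <- genotype_sim_params(n_pop1 = 8, n_pop2 = 12, chrom_length = 3e5,
                           snp_density = 0.005, n_diverged_windows = 2,
                           diverged_window_span = 40000,
                           diverged_delta = 0.5, seed = 33)
  g <- simulate_genotypes(p)
  w1 <- sweep_scan(g$variants, pop1 = "pop1")
  w2 <- sweep_scan(g$variants, pop1 = "pop2")
  expect_equal(w1$fst, w2$fst, tolerance = 1e-12)
  expect_equal(w1$pi_pop1, w2$pi_pop2, tolerance = 1e-12)
  ok <- !is.na(w1$pi_ratio) & !is.na(w2$pi_ratio) & w1$pi_ratio > 0
  expect_equal(w1$pi_ratio[ok], 1 / w2$pi_ratio[ok], tolerance = 1e-10)
})

test_that("planted diverged windows stand out from neutral ones", {
  p <- genotype_sim_params(n_pop1 = 10, n_pop2 = 10, chrom_length = 1e6,
                           snp_density = 0.01, n_diverged_windows = 5,
                           diverged_delta = 0.6, seed = 34)
  g <- simulate_genotypes(p)
  w <- sweep_scan(g$variants, chrom_lengths = c(chrSim = 1e6))
  tw <- g$truth$windows
  planted <- vapply(seq_len(nrow(w)), function(i)
    any(tw$start <= w$end[i] & tw$end >= w$start[i]), logical(1))
  usable <- !is.na(w$fst) & !w$partial
  expect_gte(mean(w$fst[planted & usable]), 0.3)
  expect_gt(mean(w$fst[planted & usable]),
            mean(w$fst[!planted & usable]))
})
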