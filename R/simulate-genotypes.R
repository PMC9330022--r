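# Two-population diploid genotype simulator with planted high-divergence
# windows, plus minimal VCF 4.2 / population-map / BED I/O.

#' Parameters for the genotype simulator
#'
#' Sites are independent biallelic SNPs on one synthetic chromosome. Neutral
#' sites share one allele frequency per site (a Beta(2, 2) draw, truncated to
#' keep both alleles segregating) in both populations; sites inside planted
#' diverged windows get population frequencies separated by `diverged_delta`
#' (p + delta/2 and p - delta/2, clipped to [0.02, 0.98] so both populations
#' stay polymorphic).
#'
#' @param n_pop1,n_pop2 diploid sample counts per population.
#' @param chrom_length chromosome length in bp.
#' @param snp_density expected SNPs per bp.
#' @param n_diverged_windows number of non-overlapping diverged windows to
#'   plant.
#' @param diverged_window_span span of each planted window in bp.
#' @param diverged_delta target allele-frequency difference inside planted
#'   windows.
#' @param missing_rate per-genotype missingness probability.
#' @param seed integer RNG seed.
#' @return validated list of class `genotype_sim_params`.
#' @export
genotype_sim_params <- function(n_pop1 = 10L, n_pop2 = 10L,
                                chrom_length = 2e6, snp_density = 0.01,
                                n_diverged_windows = 5L,
                                diverged_window_span = 40000,
                                diverged_delta = 0.6,
                                missing_rate = 0, seed = 1L) {
  p <- list(n_pop1 = as.integer(n_pop1), n_pop2 = as.integer(n_pop2),
            chrom_length = chrom_length, snp_density = snp_density,
            n_diverged_windows = as.integer(n_diverged_windows),
            diverged_window_span = diverged_window_span,
            diverged_delta = diverged_delta,
            missing_rate = missing_rate, seed = as.integer(seed))
  stopifnot(p$n_pop1 >= 1, p$n_pop2 >= 1, p$chrom_length >= 1,
            p$diverged_delta >= 0, p$diverged_delta <= 1,
            p$missing_rate >= 0, p$missing_rate < 1,
            p$n_diverged_windows >= 0, p$diverged_window_span >= 1)
  if (p$snp_density * p$chrom_length < 1)
    stop("snp_density x chrom_length must be at least 1")
  if (p$diverged_delta > 0 &&
      p$n_diverged_windows * p$diverged_window_span > p$chrom_length)
    stop("planted windows do not fit inside the chromosome")
  class(p) <- "genotype_sim_params"
  p
}

#' Simulate two-population diploid genotypes with planted diverged windows
#'
#' Genotypes are binomial(2, p) alternate-allele dosages per individual.
#' Planted windows are non-overlapping, aligned to `diverged_window_span`
#' boundaries, and recorded in the truth object; `diverged_delta = 0` yields
#' an all-neutral truth.
#'
#' @param params a [genotype_sim_params()] object.
#' @return list with `variants` (a `variant_table`: `sites` data.frame,
#'   `geno` dosage matrix sites x samples with NA for missing, `pop` factor
#'   per sample) and `truth` (`windows` data.frame with `start`, `end`,
#'   `class`).
#' @export
simulate_genotypes <- function(params) {
  stopifnot(inherits(params, "genotype_sim_params"))
  with_seed(params$seed, {
    L <- params$chrom_length
    n_sites <- max(1L, round(params$snp_density * L))
    pos <- sort(sample.int(L, n_sites))

    span <- params$diverged_window_span
    n_slots <- floor(L / span)
    starts <- integer(0)
    if (params$n_diverged_windows > 0 && params$diverged_delta > 0) {
      if (params$n_diverged_windows > n_slots)
        stop("too many diverged windows for chromosome length")
      slot <- sort(sample.int(n_slots, params$n_diverged_windows))
      starts <- (slot - 1L) * span + 1L
    }
    windows <- data.frame(start = starts, end = starts + span - 1L)
    in_div <- rep(FALSE, n_sites)
    for (s in starts) in_div[pos >= s & pos <= s + span - 1L] <- TRUE

    p_base <- pmin(pmax(stats::rbeta(n_sites, 2, 2), 0.02), 0.98)
    d <- ifelse(in_div, params$diverged_delta, 0)
    p1 <- pmin(pmax(p_base + d / 2, 0.02), 0.98)
    p2 <- pmin(pmax(p_base - d / 2, 0.02), 0.98)

    n1 <- params$n_pop1; n2 <- params$n_pop2
    g1 <- matrix(stats::rbinom(n_sites * n1, 2, rep(p1, n1)), n_sites, n1)
    g2 <- matrix(stats::rbinom(n_sites * n2, 2, rep(p2, n2)), n_sites, n2)
    geno <- cbind(g1, g2)
    if (params$missing_rate > 0) {
      miss <- matrix(stats::runif(length(geno)) < params$missing_rate,
                     nrow(geno), ncol(geno))
      geno[miss] <- NA_integer_
    }
    samples <- c(sprintf("P1_%02d", seq_len(n1)), sprintf("P2_%02d", seq_len(n2)))
    colnames(geno) <- samples
    sites <- data.frame(chrom = "chrSim", pos = pos,
                        ref = "A", alt = "G", stringsAsFactors = FALSE)
    variants <- variant_table(sites, geno,
                              pop = stats::setNames(rep(c("pop1", "pop2"),
                                                        c(n1, n2)), samples))
    truth_windows <- if (nrow(windows)) {
      data.frame(chrom = "chrSim", windows, class = "DIVERGED",
                 stringsAsFactors = FALSE)
    } else {
      data.frame(chrom = character(), start = integer(), end = integer(),
                 class = character(), stringsAsFactors = FALSE)
    }
    list(variants = variants, truth = list(windows = truth_windows))
  })
}

#' Construct a variant table
#'
#' Container for biallelic diploid genotypes with population labels: `sites`
#' holds per-site metadata (chrom, 1-based pos, ref, alt), `geno` the
#' alternate-allele dosage matrix (0/1/2, NA = missing), `pop` the population
#' label per sample. Positions must be strictly increasing within chromosome.
#'
#' @param sites data.frame with `chrom`, `pos`, `ref`, `alt`.
#' @param geno integer matrix, sites x samples.
#' @param pop named character vector of population labels per sample.
#' @return object of class `variant_table`.
#' @export
variant_table <- function(sites, geno, pop) {
  stopifnot(nrow(sites) == nrow(geno),
            all(colnames(geno) %in% names(pop)))
  for (ch in unique(sites$chrom)) {
    p <- sites$pos[sites$chrom == ch]
    if (is.unsorted(p, strictly = TRUE))
      stop("positions must be strictly increasing within chromosome ", ch)
  }
  bad <- geno[!is.na(geno)]
  if (any(bad < 0 | bad > 2)) stop("genotype dosages must be 0, 1 or 2")
  structure(list(sites = sites, geno = geno,
                 pop = pop[colnames(geno)]),
            class = "variant_table")
}

gt_string <- function(d) {
  out <- rep("./.", length(d))
  out[!is.na(d) & d == 0] <- "0/0"
  out[!is.na(d) & d == 1] <- "0/1"
  out[!is.na(d) & d == 2] <- "1/1"
  out
}

#' Write a variant table as minimal VCF 4.2
#'
#' Emits CHROM, POS, ID, REF, ALT, QUAL=".", FILTER="PASS", INFO=".",
#' FORMAT=GT and unphased diploid genotype columns.
#'
#' @param variants a [variant_table()].
#' @param path output file path (uncompressed `.vcf`).
#' @return the path, invisibly.
#' @export
write_vcf <- function(variants, path) {
  g <- variants$geno
  gt <- apply(g, 2, gt_string)
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(g))
  body <- cbind(variants$sites$chrom, variants$sites$pos,
                sprintf("site%d", seq_len(nrow(g))),
                variants$sites$ref, variants$sites$alt,
                ".", "PASS", ".", "GT", gt)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", colnames(g)), collapse = "\t")), con)
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read biallelic genotypes from a VCF plus a population map
#'
#' Parsing is delegated to `vcfR`; multi-allelic sites are rejected.
#'
#' @param vcf_path path to a VCF 4.2 file.
#' @param pop_map_path path to a two-column TSV (`sample`, `population`).
#' @return a [variant_table()].
#' @export
read_genotypes <- function(vcf_path, pop_map_path) {
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  pm <- read_pop_map(pop_map_path)
  if (nrow(vcf@fix) == 0) {
    samp <- colnames(vcf@gt)[-1]
    if (is.null(samp)) samp <- names(pm)
    geno <- matrix(NA_integer_, 0, length(samp),
                   dimnames = list(NULL, samp))
    return(variant_table(data.frame(chrom = character(), pos = integer(),
                                    ref = character(), alt = character(),
                                    stringsAsFactors = FALSE), geno, pm))
  }
  fix <- vcfR::getFIX(vcf)
  if (any(grepl(",", fix[, "ALT"], fixed = TRUE)))
    stop("multi-allelic sites are not supported")
  gt <- vcfR::extract.gt(vcf, element = "GT")
  norm <- gsub("|", "/", gt, fixed = TRUE)
  dos <- matrix(NA_integer_, nrow(norm), ncol(norm),
                dimnames = dimnames(norm))
  dos[norm %in% c("0/0")] <- 0L
  dos[norm %in% c("0/1", "1/0")] <- 1L
  dos[norm %in% c("1/1")] <- 2L
  missing <- setdiff(colnames(dos), names(pm))
  if (length(missing))
    stop("samples absent from population map: ", paste(missing, collapse = ", "))
  sites <- data.frame(chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
                      ref = fix[, "REF"], alt = fix[, "ALT"],
                      stringsAsFactors = FALSE)
  variant_table(sites, dos, pm)
}

#' Read and write population maps
#'
#' Two-column TSV mapping sample id to population label.
#'
#' @param pop named character vector (names = sample ids).
#' @param path file path.
#' @return `read_pop_map` returns a named character vector.
#' @export
write_pop_map <- function(pop, path) {
  utils::write.table(data.frame(sample = names(pop), population = unname(pop)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pop_map
#' @export
read_pop_map <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  stats::setNames(df$population, df$sample)
}

#' Write gene intervals as BED
#'
#' BED is 0-based half-open; `genes` uses the package's 1-based inclusive
#' convention and is converted on the way out.
#'
#' @param genes data.frame with `chrom`, `start`, `end` (1-based inclusive),
#'   `gene_id`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_bed <- function(genes, path) {
  utils::write.table(
    data.frame(genes$chrom, genes$start - 1L, genes$end, genes$gene_id),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
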