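# Two-population windowed selective-sweep scan: Weir-Cockerham Fst,
# per-population nucleotide diversity, sliding windows, region calling and
# gene annotation.

#' Per-site Weir-Cockerham Fst variance components
#'
#' Two-population form of the 1984 variance-components estimator. For each
#' site the function returns the among-population component `a` and the
#' total `a + b + c`; the windowed estimator is the ratio of their sums.
#' Sites monomorphic across both populations return (0, 0) and are skipped
#' in the ratio; sites where either population has no called genotypes (or
#' fewer than two called alleles in total) return NA.
#'
#' @param n1,n2 called diploid sample sizes per population (vectors over
#'   sites).
#' @param ac1,ac2 alternate-allele counts (0..2n).
#' @param het1,het2 heterozygote counts.
#' @return data.frame with columns `a` and `d` (= a + b + c).
#' @export
site_fst_components <- function(n1, ac1, het1, n2, ac2, het2) {
  p1 <- ac1 / (2 * n1)
  p2 <- ac2 / (2 * n2)
  h1 <- het1 / n1
  h2 <- het2 / n2
  nbar <- (n1 + n2) / 2
  r <- 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  out_a <- a
  out_d <- a + b + cc
  mono <- !is.na(pbar) & (pbar <= 0 | pbar >= 1)
  out_a[mono] <- 0
  out_d[mono] <- 0
  bad <- is.na(n1) | is.na(n2) | n1 < 1 | n2 < 1 | nbar <= 1
  out_a[bad] <- NA_real_
  out_d[bad] <- NA_real_
  data.frame(a = out_a, d = out_d)
}

#' Windowed Fst from site components
#'
#' Ratio-of-sums aggregation: sum of among-population components over the
#' sum of totals, for the usable (non-NA, polymorphic-total) sites of one
#' window. Returns NA when the window has no usable polymorphic site.
#'
#' @param components data.frame from [site_fst_components()] for the sites
#'   in one window.
#' @param clamp clamp the ratio into [0, 1] (default TRUE; the raw ratio
#'   can be slightly negative by sampling noise).
#' @return single Fst value or NA.
#' @export
window_fst <- function(components, clamp = TRUE) {
  ok <- !is.na(components$a) & !is.na(components$d) & components$d != 0
  if (!any(ok)) return(NA_real_)
  fst <- sum(components$a[ok]) / sum(components$d[ok])
  if (clamp) fst <- min(1, max(0, fst))
  fst
}

#' Per-site nucleotide diversity of one window
#'
#' Unbiased per-site heterozygosity `2 p (1 - p) * 2n / (2n - 1)` summed
#' over sites and divided by the window length in bp. Sites with fewer than
#' two called alleles in the population are skipped.
#'
#' @param n called diploid sample sizes per site.
#' @param ac alternate-allele counts per site.
#' @param window_length window span in bp.
#' @return per-site nucleotide diversity (>= 0).
#' @export
window_pi <- function(n, ac, window_length) {
  stopifnot(window_length > 0)
  ok <- !is.na(n) & n >= 1
  if (!any(ok)) return(0)
  n <- n[ok]; ac <- ac[ok]
  p <- ac / (2 * n)
  sum(2 * p * (1 - p) * (2 * n) / (2 * n - 1)) / window_length
}

#' Sliding windows over chromosomes
#'
#' Windows start at 1, 1 + step, ... and have the given span; the terminal
#' window that extends past the chromosome end is retained and flagged
#' `partial`.
#'
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#' @param window window span in bp.
#' @param step step size in bp (`window >= step > 0`).
#' @return data.frame `chrom`, `start`, `end` (1-based inclusive),
#'   `partial`.
#' @export
make_windows <- function(chrom_lengths, window = 40000, step = 20000) {
  stopifnot(window >= step, step > 0)
  rows <- lapply(names(chrom_lengths), function(ch) {
    L <- chrom_lengths[[ch]]
    starts <- seq(1, L, by = step)
    data.frame(chrom = ch, start = starts, end = starts + window - 1,
               partial = starts + window - 1 > L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Per-site per-population summaries from a variant_table: called diploids,
# alt-allele counts, heterozygote counts.
site_pop_stats <- function(variants, pop_label) {
  g <- variants$geno[, variants$pop == pop_label, drop = FALSE]
  called <- !is.na(g)
  list(n = rowSums(called),
       ac = rowSums(g, na.rm = TRUE),
       het = rowSums(g == 1, na.rm = TRUE))
}

#' Windowed two-population sweep scan
#'
#' Computes per-window Weir-Cockerham Fst (ratio of sums), per-population
#' nucleotide diversity, and the diversity ratio `pi_pop2 / pi_pop1`, where
#' `pop1` is by convention the putatively selected (highland) population so
#' the ratio reads lowland-over-highland.
#'
#' @param variants a [variant_table()] with exactly two population labels.
#' @param window,step window span and step in bp.
#' @param chrom_lengths optional named lengths; default: the largest
#'   observed position per chromosome.
#' @param pop1 population treated as pop1 (default: first label
#'   encountered).
#' @return data.frame of per-window statistics: `chrom`, `start`, `end`,
#'   `partial`, `n_sites`, `fst_raw`, `fst` (clamped to [0, 1]),
#'   `pi_pop1`, `pi_pop2`, `pi_ratio`.
#' @export
sweep_scan <- function(variants, window = 40000, step = 20000,
                       chrom_lengths = NULL, pop1 = NULL) {
  pops <- unique(unname(variants$pop))
  if (length(pops) != 2) stop("exactly two populations are required")
  if (is.null(pop1)) pop1 <- pops[1]
  if (!pop1 %in% pops) stop("unknown population: ", pop1)
  pop2 <- setdiff(pops, pop1)
  s1 <- site_pop_stats(variants, pop1)
  s2 <- site_pop_stats(variants, pop2)
  comp <- site_fst_components(s1$n, s1$ac, s1$het, s2$n, s2$ac, s2$het)
  if (is.null(chrom_lengths))
    chrom_lengths <- tapply(variants$sites$pos, variants$sites$chrom, max)
  if (!length(chrom_lengths)) {
    out <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), partial = logical(),
                      n_sites = integer(), fst_raw = numeric(),
                      fst = numeric(), pi_pop1 = numeric(),
                      pi_pop2 = numeric(), pi_ratio = numeric(),
                      stringsAsFactors = FALSE)
    attr(out, "pop1") <- pop1
    attr(out, "pop2") <- pop2
    return(out)
  }
  win <- make_windows(chrom_lengths, window, step)
  stats_rows <- lapply(seq_len(nrow(win)), function(i) {
    in_w <- variants$sites$chrom == win$chrom[i] &
      variants$sites$pos >= win$start[i] & variants$sites$pos <= win$end[i]
    idx <- which(in_w)
    fst_raw <- window_fst(comp[idx, , drop = FALSE], clamp = FALSE)
    pi1 <- window_pi(s1$n[idx], s1$ac[idx], window)
    pi2 <- window_pi(s2$n[idx], s2$ac[idx], window)
    data.frame(n_sites = length(idx), fst_raw = fst_raw,
               fst = if (is.na(fst_raw)) NA_real_ else min(1, max(0, fst_raw)),
               pi_pop1 = pi1, pi_pop2 = pi2,
               pi_ratio = if (pi1 > 0) pi2 / pi1 else NA_real_)
  })
  out <- cbind(win, do.call(rbind, stats_rows))
  attr(out, "pop1") <- pop1
  attr(out, "pop2") <- pop2
  out
}

#' Call candidate sweep regions from window statistics
#'
#' Windows with (clamped) Fst at or above the threshold are merged into
#' regions when they overlap or are book-ended on the same chromosome.
#' Partial terminal windows are excluded by default.
#'
#' @param windows data.frame from [sweep_scan()].
#' @param fst_threshold minimum window Fst (inclusive).
#' @param include_partial include flagged partial windows.
#' @return data.frame `chrom`, `start`, `end`, `n_windows`, `peak_fst`.
#' @export
call_regions <- function(windows, fst_threshold = 0.3,
                         include_partial = FALSE) {
  qual <- !is.na(windows$fst) & windows$fst >= fst_threshold &
    (include_partial | !windows$partial)
  q <- windows[qual, , drop = FALSE]
  if (!nrow(q))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), n_windows = integer(),
                      peak_fst = numeric(), stringsAsFactors = FALSE))
  gr <- GenomicRanges::GRanges(q$chrom, IRanges::IRanges(q$start, q$end))
  red <- GenomicRanges::reduce(gr)
  hits <- GenomicRanges::findOverlaps(red, gr)
  peak <- tapply(q$fst[S4Vectors::subjectHits(hits)],
                 S4Vectors::queryHits(hits), max)
  nwin <- tapply(S4Vectors::subjectHits(hits),
                 S4Vectors::queryHits(hits), length)
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(red)),
                    start = GenomicRanges::start(red),
                    end = GenomicRanges::end(red),
                    n_windows = as.integer(nwin),
                    peak_fst = as.numeric(peak),
                    stringsAsFactors = FALSE)
  out[order(out$chrom, out$start), , drop = FALSE]
}

read_gene_intervals <- function(annotation) {
  if (is.data.frame(annotation)) {
    stopifnot(all(c("chrom", "start", "end", "gene_id") %in% names(annotation)))
    return(annotation)
  }
  ext <- tolower(tools::file_ext(annotation))
  if (ext == "bed") {
    gr <- rtracklayer::import(annotation, format = "bed")
    ids <- if (!is.null(gr$name)) gr$name else as.character(seq_along(gr))
  } else if (ext %in% c("gff", "gff3", "gtf")) {
    gr <- rtracklayer::import(annotation)
    ids <- if (!is.null(gr$gene_id)) gr$gene_id
           else if (!is.null(gr$ID)) gr$ID
           else if (!is.null(gr$Name)) gr$Name
           else as.character(seq_along(gr))
  } else {
    stop("unknown annotation format: ", annotation)
  }
  # rtracklayer imports both BED and GFF as 1-based inclusive ranges
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             gene_id = as.character(ids), stringsAsFactors = FALSE)
}

#' Annotate sweep regions with overlapping genes
#'
#' A gene is attached when its interval overlaps a region by at least 1 bp
#' (both in the package's 1-based inclusive convention; BED input is
#' converted on import). A gene spanning several regions appears in each
#' but counts once in the unique-gene attribute.
#'
#' @param regions data.frame from [call_regions()].
#' @param annotation BED/GFF file path or a data.frame with `chrom`,
#'   `start`, `end` (1-based inclusive), `gene_id`.
#' @return regions with a `genes` column (comma-separated ids); attribute
#'   `"n_genes"` holds the unique gene count.
#' @export
annotate_regions <- function(regions, annotation) {
  genes <- read_gene_intervals(annotation)
  if (!nrow(regions)) {
    regions$genes <- character(0)
    attr(regions, "n_genes") <- 0L
    return(regions)
  }
  rgr <- GenomicRanges::GRanges(regions$chrom,
                                IRanges::IRanges(regions$start, regions$end))
  ggr <- GenomicRanges::GRanges(genes$chrom,
                                IRanges::IRanges(genes$start, genes$end))
  hits <- GenomicRanges::findOverlaps(rgr, ggr)
  gl <- rep("", nrow(regions))
  if (length(hits)) {
    by_region <- split(genes$gene_id[S4Vectors::subjectHits(hits)],
                       S4Vectors::queryHits(hits))
    for (k in names(by_region))
      gl[as.integer(k)] <- paste(sort(unique(by_region[[k]])), collapse = ",")
  }
  regions$genes <- gl
  attr(regions, "n_genes") <-
    length(unique(genes$gene_id[S4Vectors::subjectHits(hits)]))
  regions
}
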