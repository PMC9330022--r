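# End-to-end orchestration: config validation, the transcriptome screen
# pipeline (normalize -> test -> screen -> ANOVA) and the sweep pipeline.

config_schema <- list(
  counts = NULL, design = NULL, out_dir = NULL, seed = NULL,
  anova_alpha = NULL,
  de = c("min_abs_log2fc", "min_log2cpm", "max_fdr"),
  deg = c("min_fc", "alpha"),
  screen = c("membership_dir"),
  sweep = c("vcf", "pop_map", "annotation", "window", "step", "fst_min",
            "include_partial", "pop1")
)

#' Load and validate a pipeline configuration
#'
#' Accepts a YAML file path or a list. Unknown keys (top level or nested)
#' are rejected; defaults are filled for everything optional. `seed` drives
#' every stochastic stage.
#'
#' @param x YAML path or list.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(x) {
  if (is.character(x) && !file.exists(x))
    stop("config error: config file not found: ", x)
  cfg <- if (is.character(x)) yaml::read_yaml(x) else x
  if (!is.list(cfg)) stop("config must be a list or a YAML file")
  unknown <- setdiff(names(cfg), names(config_schema))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  for (sec in c("de", "deg", "screen", "sweep")) {
    if (!is.null(cfg[[sec]])) {
      bad <- setdiff(names(cfg[[sec]]), config_schema[[sec]])
      if (length(bad))
        stop("unknown key(s) in '", sec, "': ", paste(bad, collapse = ", "))
    }
  }
  defaults <- list(out_dir = ".", seed = 1L, anova_alpha = 0.05,
                   de = list(min_abs_log2fc = 1.5, min_log2cpm = 2,
                             max_fdr = 0.05),
                   deg = list(min_fc = 2, alpha = 0.05),
                   sweep = list(window = 40000, step = 20000, fst_min = 0.3,
                                include_partial = FALSE))
  for (k in names(defaults)) {
    if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
    else if (is.list(defaults[[k]]))
      for (kk in setdiff(names(defaults[[k]]), names(cfg[[k]])))
        cfg[[k]][[kk]] <- defaults[[k]][[kk]]
  }
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "pipeline_config"
  cfg
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(unclass(cfg)), tmp)
  unname(tools::md5sum(tmp))
}

pkg_version <- function() {
  as.character(utils::packageVersion("plastisweep"))
}

# Every pipeline output starts with a provenance comment.
write_output_tsv <- function(df, path, cfg) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# plastisweep %s config_hash=%s seed=%d",
                     pkg_version(), config_hash(cfg), cfg$seed), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pipeline output TSV
#'
#' Skips the provenance comment header.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_output_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

subset_norm <- function(norm, samples) {
  structure(list(factors = norm$factors[samples],
                 lib_sizes = norm$lib_sizes[samples],
                 ref_sample = norm$ref_sample),
            class = "norm_factors")
}

#' Run the transcriptome screen pipeline
#'
#' For each tissue: TMM normalization, common-dispersion estimation across
#' the four groups, the six pairwise NB exact tests with DEM calling, the
#' effective/ineffective intersection screen, and the two-way ANOVA
#' classification of candidates on log2-CPM. All intermediates are written
#' under `out_dir`. With `membership_dir` set in the `screen` section, the
#' DE stage is bypassed and per-tissue membership tables named
#' `membership_<tissue>.tsv` are read instead (fixture-injection mode for
#' regression testing against known screen outcomes).
#'
#' @param config a [pipeline_config()] (or path/list accepted by it).
#' @param dry_run validate the config and input formats, run nothing.
#' @return invisible list with per-tissue `candidates`, `anova`, `enms`
#'   (final calls), or NULL in fixture mode without counts.
#' @export
run_transcriptome <- function(config, dry_run = FALSE) {
  cfg <- pipeline_config(config)
  if (is.null(cfg$counts) || is.null(cfg$design))
    stop("config error: 'counts' and 'design' paths are required")
  for (p in c(cfg$counts, cfg$design))
    if (!file.exists(p)) stop("data error: input not found: ", p)
  counts <- read_counts(cfg$counts)
  design <- read_design(cfg$design)
  if (!setequal(colnames(counts), design$sample_id))
    stop("data error: count columns and design sample_ids differ")
  if (dry_run) {
    message("dry-run ok: ", nrow(counts), " features, ",
            ncol(counts), " samples")
    return(invisible(NULL))
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  thr <- de_thresholds(cfg$de$min_abs_log2fc, cfg$de$min_log2cpm,
                       cfg$de$max_fdr)
  results <- list()
  for (tis in unique(design$tissue)) {
    d <- design[design$tissue == tis, ]
    cts <- counts[, d$sample_id, drop = FALSE]
    screen <- build_screen_design(d)
    norm <- tmm_factors(cts)
    phi <- estimate_common_dispersion(cts, d$group, norm)
    write_output_tsv(
      data.frame(sample = names(norm$factors), factor = norm$factors,
                 lib_size = norm$lib_sizes, dispersion = phi),
      file.path(cfg$out_dir, paste0("norm_", tis, ".tsv")), cfg)
    de_sets <- list()
    for (i in seq_len(nrow(screen))) {
      ga <- d$sample_id[d$group == screen$group_a[i]]
      gb <- d$sample_id[d$group == screen$group_b[i]]
      res <- nb_exact_test(cts, ga, gb, phi,
                           norm = subset_norm(norm, c(ga, gb)),
                           comparison = screen$comparison[i])
      res <- call_dems(res, thr)
      write_output_tsv(res, file.path(cfg$out_dir,
                                      sprintf("de_%s_%s.tsv", tis,
                                              screen$comparison[i])), cfg)
      de_sets[[screen$comparison[i]]] <- res
    }
    write_output_tsv(membership_table(de_sets, screen),
                     file.path(cfg$out_dir,
                               paste0("membership_", tis, ".tsv")), cfg)
    cand <- screen_enm(de_sets, screen)
    if (nrow(cand)) {
      lcpm <- cpm_matrix(cts, norm, log = TRUE)
      an <- anova_table(lcpm, d, features = cand$feature)
      final <- classify_candidates(cand, an, cfg$anova_alpha)
    } else {
      an <- data.frame()
      final <- cand
      final$p_breed <- numeric(0)
      final$p_env <- numeric(0)
      final$p_int <- numeric(0)
      final$enm <- logical(0)
    }
    out_tab <- if (nrow(final)) cbind(tissue = tis, final) else
      data.frame(tissue = character(0), final)
    write_output_tsv(out_tab,
                     file.path(cfg$out_dir,
                               paste0("candidates_", tis, ".tsv")), cfg)
    results[[tis]] <- list(candidates = cand, anova = an, enms = final)
  }
  invisible(results)
}

#' Run the screen on injected membership tables
#'
#' Fixture-injection mode: the DE stage is bypassed and per-comparison DE
#' membership (with directions) is taken as given, so known worked examples
#' exercise the screen logic independently of any count data.
#'
#' @param de_sets_by_tissue named list (tissue -> de_sets as accepted by
#'   [screen_enm()]).
#' @param design sample design data.frame (for the group structure).
#' @return data.frame of candidates across tissues with a `tissue` column.
#' @export
run_screen_fixtures <- function(de_sets_by_tissue, design) {
  screen <- build_screen_design(design)
  rows <- lapply(names(de_sets_by_tissue), function(tis) {
    cand <- screen_enm(de_sets_by_tissue[[tis]], screen)
    if (nrow(cand)) cbind(tissue = tis, cand) else NULL
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(tissue = character(), feature = character(),
                      altitude_preference = character(),
                      support = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Run the selective-sweep pipeline
#'
#' Reads genotypes and the population map, computes windowed Fst and
#' nucleotide diversity, calls regions at the Fst threshold, annotates them
#' with gene intervals when an annotation is configured, and writes the
#' window and region tables.
#'
#' @inheritParams run_transcriptome
#' @return invisible list with `windows`, `regions`.
#' @export
run_sweep <- function(config, dry_run = FALSE) {
  cfg <- pipeline_config(config)
  sw <- cfg$sweep
  if (is.null(sw$vcf) || is.null(sw$pop_map))
    stop("config error: sweep.vcf and sweep.pop_map are required")
  for (p in c(sw$vcf, sw$pop_map))
    if (!file.exists(p)) stop("data error: input not found: ", p)
  variants <- read_genotypes(sw$vcf, sw$pop_map)
  if (dry_run) {
    message("dry-run ok: ", nrow(variants$sites), " sites, ",
            ncol(variants$geno), " samples")
    return(invisible(NULL))
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  windows <- sweep_scan(variants, window = sw$window, step = sw$step,
                        pop1 = sw$pop1)
  regions <- call_regions(windows, fst_threshold = sw$fst_min,
                          include_partial = isTRUE(sw$include_partial))
  n_genes <- NA_integer_
  if (!is.null(sw$annotation)) {
    regions <- annotate_regions(regions, sw$annotation)
    n_genes <- attr(regions, "n_genes")
  }
  write_output_tsv(windows, file.path(cfg$out_dir, "windows.tsv"), cfg)
  write_output_tsv(regions, file.path(cfg$out_dir, "regions.tsv"), cfg)
  message(sprintf(
    "windows=%d qualifying=%d regions=%d unique_genes=%s",
    nrow(windows),
    sum(!is.na(windows$fst) & windows$fst >= sw$fst_min & !windows$partial),
    nrow(regions), ifelse(is.na(n_genes), "NA", n_genes)))
  invisible(list(windows = windows, regions = regions))
}
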