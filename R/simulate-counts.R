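# Synthetic negative-binomial count matrices with planted breed/environment
# effects and full ground truth.

# Evaluate `code` under `set.seed(seed)`, restoring the caller's RNG state so
# simulation calls do not perturb an enclosing analysis.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

#' Parameters for the count simulator
#'
#' The defaults emulate a small-RNA reciprocal-transplant experiment: three
#' replicates per (breed, env, tissue) cell, moderate biological
#' overdispersion (NB variance mu + phi*mu^2 with a single common phi), a
#' two-fold-per-log2-unit planted effect of 2 log2 units, and library sizes
#' near one million reads.
#'
#' @param n_features number of features (miRNAs) to simulate.
#' @param n_reps replicates per design cell (used when building a default
#'   design, see [simulate_counts()]).
#' @param baseline_log2_mean_range interval of per-feature baseline log2 mean
#'   counts, drawn uniformly.
#' @param dispersion common NB dispersion phi (variance = mu + phi mu^2).
#' @param frac_en,frac_br,frac_int fractions of features with a pure
#'   environment effect, a pure breed effect, and a single-cell interaction
#'   effect; they must sum to at most 1.
#' @param effect_log2fc absolute planted effect size in log2 units.
#' @param lib_size_range interval of per-sample library sizes, drawn
#'   uniformly (integers).
#' @param seed integer RNG seed.
#' @return a validated list of class `count_sim_params`.
#' @export
count_sim_params <- function(n_features = 1000L, n_reps = 3L,
                             baseline_log2_mean_range = c(4, 10),
                             dispersion = 0.05,
                             frac_en = 0.05, frac_br = 0.05, frac_int = 0.05,
                             effect_log2fc = 2,
                             lib_size_range = c(8e5, 1.2e6),
                             seed = 1L) {
  p <- list(n_features = as.integer(n_features), n_reps = as.integer(n_reps),
            baseline_log2_mean_range = baseline_log2_mean_range,
            dispersion = dispersion, frac_en = frac_en, frac_br = frac_br,
            frac_int = frac_int, effect_log2fc = effect_log2fc,
            lib_size_range = lib_size_range, seed = as.integer(seed))
  stopifnot(p$n_features >= 1, p$n_reps >= 1,
            length(p$baseline_log2_mean_range) == 2,
            diff(p$baseline_log2_mean_range) >= 0,
            p$dispersion >= 0, p$effect_log2fc > 0,
            length(p$lib_size_range) == 2, all(p$lib_size_range >= 1))
  fr <- c(p$frac_en, p$frac_br, p$frac_int)
  if (any(fr < 0) || any(fr > 1) || sum(fr) > 1)
    stop("feature-class fractions must lie in [0,1] and sum to at most 1")
  class(p) <- "count_sim_params"
  p
}

#' Simulate an NB count matrix over a transplant design
#'
#' Counts are negative-binomial draws with per-sample library-size scaling.
#' A fraction of features carries a pure environment effect (mean shifted by
#' `±effect_log2fc` between HIGH and LOW samples regardless of breed), a
#' fraction a pure breed effect (TIB vs PX regardless of environment), and a
#' fraction an interaction effect confined to the TIB+HIGH cell. The truth
#' object records each feature's class and effect direction, plus the planted
#' library sizes.
#'
#' @param params a [count_sim_params()] object.
#' @param design sample design data.frame covering the 2x2 factorial for at
#'   least one tissue; defaults to a single-tissue design with
#'   `params$n_reps` replicates.
#' @return list with `counts` (integer matrix, features x samples), `design`,
#'   and `truth` (`feature_class`, `effect_direction`, `lib_sizes`).
#' @export
simulate_counts <- function(params, design = NULL) {
  stopifnot(inherits(params, "count_sim_params"))
  if (is.null(design))
    design <- make_sample_design(tissues = "liver", n_reps = params$n_reps)
  validate_design(design)
  cells <- table(design$breed, design$env)
  if (any(cells == 0)) {
    bad <- which(cells == 0, arr.ind = TRUE)
    stop("design is not factorial: missing cell ",
         rownames(cells)[bad[1, 1]], "+", colnames(cells)[bad[1, 2]])
  }

  n <- params$n_features
  m <- nrow(design)
  with_seed(params$seed, {
    n_en <- round(params$frac_en * n)
    n_br <- round(params$frac_br * n)
    n_int <- round(params$frac_int * n)
    cls <- rep("NULL", n)
    cls[seq_len(n_en)] <- "EN"
    cls[n_en + seq_len(n_br)] <- "BR"
    cls[n_en + n_br + seq_len(n_int)] <- "INT"
    direction <- sample(c(-1L, 1L), n, replace = TRUE)
    direction[cls == "NULL"] <- 0L

    base_log2 <- stats::runif(n, params$baseline_log2_mean_range[1],
                              params$baseline_log2_mean_range[2])
    lib <- round(stats::runif(m, params$lib_size_range[1],
                              params$lib_size_range[2]))

    # log2 offset per feature x sample; effects are symmetric around the
    # baseline (+e/2 on one side, -e/2 on the other) so logCPM is preserved
    half <- params$effect_log2fc / 2
    hi <- design$env == "HIGH"
    tib <- design$breed == "TIB"
    offset <- matrix(0, n, m)
    en_rows <- which(cls == "EN")
    br_rows <- which(cls == "BR")
    int_rows <- which(cls == "INT")
    if (length(en_rows))
      offset[en_rows, ] <- outer(direction[en_rows] * half,
                                 ifelse(hi, 1, -1))
    if (length(br_rows))
      offset[br_rows, ] <- outer(direction[br_rows] * half,
                                 ifelse(tib, 1, -1))
    if (length(int_rows))
      offset[int_rows, ] <- outer(direction[int_rows] * params$effect_log2fc,
                                  as.numeric(hi & tib))

    rel <- lib / mean(lib)
    mu <- 2^(base_log2 + offset) * rep(rel, each = n)
    counts <- if (params$dispersion == 0) {
      matrix(stats::rpois(n * m, mu), n, m)
    } else {
      matrix(stats::rnbinom(n * m, size = 1 / params$dispersion, mu = mu),
             n, m)
    }
    feat <- sprintf("feat_%04d", seq_len(n))
    storage.mode(counts) <- "integer"
    dimnames(counts) <- list(feat, design$sample_id)
    truth <- list(
      feature_class = stats::setNames(cls, feat),
      effect_direction = stats::setNames(direction, feat),
      lib_sizes = stats::setNames(lib, design$sample_id)
    )
    list(counts = counts, design = design, truth = truth)
  })
}

#' Read and write count matrices
#'
#' TSV with feature ids in the first column (`feature`) and one column per
#' sample. Round-trips exactly for integer counts.
#'
#' @param counts integer matrix, features x samples, with dimnames.
#' @param path file path.
#' @return `read_counts` returns an integer matrix with dimnames.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(feature = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df[[1]]
  if (any(m < 0, na.rm = TRUE)) stop("negative counts in ", path)
  m
}
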