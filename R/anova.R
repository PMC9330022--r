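# Two-way breed x environment ANOVA for screen candidates, and the final
# ENM classification.

#' Two-way breed-by-environment ANOVA for one feature
#'
#' Fits `value ~ breed * env` with [stats::aov()] on a complete, balanced
#' 2x2 design (type-I sums of squares, which equal type-III under balance)
#' and returns F and p for the breed main effect, the environment main
#' effect and their interaction, plus the four cell means. Degenerate
#' zero-residual fits are resolved by convention: an effect with zero sum of
#' squares gets F = 0, p = 1; a non-zero effect over zero residual gets
#' F = Inf, p = 0.
#'
#' @param values numeric response per sample (one feature, typically
#'   log2-CPM).
#' @param breed,env factors (or coercible) per sample.
#' @return one-row data.frame: `f_breed`, `p_breed`, `f_env`, `p_env`,
#'   `f_int`, `p_int`, the four sums of squares (`ss_breed`, `ss_env`,
#'   `ss_int`, `ss_resid`), and `mean_<breed>_<env>` cell means.
#' @export
two_way_anova <- function(values, breed, env) {
  breed <- factor(breed); env <- factor(env)
  stopifnot(length(values) == length(breed), length(breed) == length(env))
  tab <- table(breed, env)
  if (nrow(tab) != 2 || ncol(tab) != 2 || any(tab == 0))
    stop("design must cover all four (breed, env) cells")
  if (length(unique(as.vector(tab))) != 1)
    stop("design must be balanced (equal replicates per cell)")
  fit <- stats::aov(values ~ breed * env)
  # perfect fits trigger a warning from anova.lm; those F statistics are
  # replaced below by the documented zero-residual conventions
  an <- withCallingHandlers(
    stats::anova(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  ss <- an[["Sum Sq"]]; df <- an[["Df"]]
  ms <- ss / df
  # a sum of squares is "zero" when it is at rounding-noise scale relative
  # to the magnitude of the response itself
  eps <- 1e-12 * (sum(values^2) + 1)
  zero <- ss <= eps
  fp <- function(i) {
    if (!zero[4]) {
      f <- ms[i] / ms[4]
      c(f, stats::pf(f, df[i], df[4], lower.tail = FALSE))
    } else if (zero[i]) {
      c(0, 1)
    } else {
      c(Inf, 0)
    }
  }
  b <- fp(1); e <- fp(2); i <- fp(3)
  cells <- tapply(values, list(breed, env), mean)
  out <- data.frame(f_breed = b[1], p_breed = b[2],
                    f_env = e[1], p_env = e[2],
                    f_int = i[1], p_int = i[2],
                    ss_breed = ss[1], ss_env = ss[2], ss_int = ss[3],
                    ss_resid = ss[4])
  for (br in rownames(cells))
    for (en in colnames(cells))
      out[[paste("mean", br, en, sep = "_")]] <- cells[br, en]
  out
}

#' Two-way ANOVA over a set of features
#'
#' Applies [two_way_anova()] row-wise to an expression matrix.
#'
#' @param expr features x samples matrix (typically log2-CPM).
#' @param design sample design data.frame matching the columns of `expr`.
#' @param features optional subset of feature ids (default: all rows).
#' @return data.frame with one row per feature, `feature` first.
#' @export
anova_table <- function(expr, design, features = NULL) {
  stopifnot(all(colnames(expr) %in% design$sample_id))
  d <- design[match(colnames(expr), design$sample_id), ]
  if (is.null(features)) features <- rownames(expr)
  missing <- setdiff(features, rownames(expr))
  if (length(missing))
    stop("features absent from expression matrix: ",
         paste(missing, collapse = ", "))
  rows <- lapply(features, function(f)
    cbind(data.frame(feature = f, stringsAsFactors = FALSE),
          two_way_anova(expr[f, ], d$breed, d$env)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Final ENM classification of screen candidates
#'
#' A candidate is confirmed as an environment-driven miRNA when its
#' environment main effect is significant and its breed main effect is not.
#' Interaction significance is reported but does not enter the call.
#'
#' @param candidates data.frame from [screen_enm()].
#' @param anova data.frame from [anova_table()] covering every candidate.
#' @param alpha significance level for both main effects.
#' @return candidates joined with the ANOVA p-values and a logical `enm`
#'   column.
#' @export
classify_candidates <- function(candidates, anova, alpha = 0.05) {
  stopifnot(alpha > 0, alpha <= 1)
  idx <- match(candidates$feature, anova$feature)
  if (anyNA(idx))
    stop("no ANOVA row for candidate(s): ",
         paste(candidates$feature[is.na(idx)], collapse = ", "))
  out <- cbind(candidates,
               anova[idx, c("p_breed", "p_env", "p_int"), drop = FALSE])
  out$enm <- out$p_env <= alpha & out$p_breed > alpha
  rownames(out) <- NULL
  out
}
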