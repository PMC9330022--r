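# The effective/ineffective comparison screen for environment-driven
# miRNAs (ENMs).
#
# In the 2x2 reciprocal-transplant design the six pairwise group comparisons
# decompose into additive factors: breed (BR) when the two groups differ in
# breed, environment (EN) when they differ in rearing environment, and
# experimental error (EE) always. The four EN-bearing comparisons are the
# "effective" ones; the two same-environment comparisons are "ineffective".
# A candidate ENM must be differentially expressed in every effective
# comparison and in neither ineffective one.

#' Build the effective/ineffective comparison structure
#'
#' Derives the six unordered group comparisons and their factor incidence
#' from the (breed, env) composition of each group — never from the group
#' labels. Comparisons are canonicalized with the high-environment group
#' first; same-environment pairs put the TIB group first.
#'
#' @param design sample design data.frame covering all four groups.
#' @return data.frame of class `screen_design` with one row per comparison:
#'   `comparison`, `group_a`, `group_b`, `factors` (comma string containing
#'   `EE` always, plus `BR`/`EN`), `effective` (logical: EN present).
#' @export
build_screen_design <- function(design) {
  groups <- unique(design[, c("group", "breed", "env")])
  if (nrow(groups) != 4)
    stop("all four (breed, env) groups are required; found ",
         paste(groups$group, collapse = ", "))
  rownames(groups) <- groups$group
  pairs <- utils::combn(groups$group, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    env_a <- groups[a, "env"]; env_b <- groups[b, "env"]
    breed_a <- groups[a, "breed"]; breed_b <- groups[b, "breed"]
    diff_env <- env_a != env_b
    diff_breed <- breed_a != breed_b
    # canonical orientation
    if (diff_env) {
      if (env_b == "HIGH") { tmp <- a; a <- b; b <- tmp }
    } else if (groups[b, "breed"] == "TIB") {
      tmp <- a; a <- b; b <- tmp
    }
    fac <- c(if (diff_breed) "BR", if (diff_env) "EN", "EE")
    data.frame(comparison = paste0(a, "-", b), group_a = a, group_b = b,
               factors = paste(fac, collapse = ","),
               effective = diff_env, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(!out$effective, out$comparison), ]
  rownames(out) <- NULL
  class(out) <- c("screen_design", "data.frame")
  out
}

# Reconcile user-supplied per-comparison DE sets (arbitrary orientation in
# the names, e.g. "LC-TC") with the canonical screen design. Returns a list
# keyed by canonical comparison of data.frames (feature, direction) where
# direction is relative to the canonical group_a.
canonicalize_de_sets <- function(de_sets, screen) {
  out <- stats::setNames(vector("list", nrow(screen)), screen$comparison)
  for (nm in names(de_sets)) {
    parts <- strsplit(nm, "-", fixed = TRUE)[[1]]
    if (length(parts) != 2)
      stop("comparison name not of the form A-B: ", nm)
    hit <- which((screen$group_a == parts[1] & screen$group_b == parts[2]) |
                   (screen$group_a == parts[2] & screen$group_b == parts[1]))
    if (!length(hit)) stop("comparison not in the design: ", nm)
    df <- de_sets[[nm]]
    if (!is.null(df$de)) df <- df[df$de, , drop = FALSE]
    dir <- if (nrow(df)) df$direction else character(0)
    if (screen$group_a[hit] != parts[1]) {
      dir <- ifelse(is.na(dir), dir,
                    ifelse(dir == "UP_IN_A", "UP_IN_B",
                           ifelse(dir == "UP_IN_B", "UP_IN_A", dir)))
    }
    out[[screen$comparison[hit]]] <-
      data.frame(feature = df$feature, direction = dir,
                 stringsAsFactors = FALSE)
  }
  missing <- names(out)[vapply(out, is.null, logical(1))]
  if (length(missing))
    stop("missing comparisons: ", paste(missing, collapse = ", "))
  out
}

#' Intersection of the effective DE sets
#'
#' The intermediate of the screen: features differentially expressed in all
#' four environment-bearing comparisons.
#'
#' @param de_sets named list of per-comparison DE tables ([call_dems()]
#'   output, or data.frames with `feature` and `direction`). Names are
#'   comparison labels in either orientation.
#' @param screen a [build_screen_design()] result.
#' @return character vector of feature ids.
#' @export
intersect_effective <- function(de_sets, screen) {
  cs <- canonicalize_de_sets(de_sets, screen)
  eff <- screen$comparison[screen$effective]
  Reduce(intersect, lapply(cs[eff], function(d) d$feature))
}

#' Screen for candidate environment-driven miRNAs
#'
#' A feature is a candidate iff it is in every effective DE set and in
#' neither ineffective DE set. Altitude preference is `HIGH` when the
#' high-environment group is the up-regulated side in all four effective
#' comparisons, `LOW` when it never is, otherwise `INCONSISTENT` (kept and
#' flagged, not dropped).
#'
#' @inheritParams intersect_effective
#' @return data.frame with `feature`, `altitude_preference`, `support`
#'   (per-comparison directions, `comparison=UP_HIGH|UP_LOW`).
#' @export
screen_enm <- function(de_sets, screen) {
  cs <- canonicalize_de_sets(de_sets, screen)
  eff <- screen$comparison[screen$effective]
  ineff <- screen$comparison[!screen$effective]
  cand <- Reduce(intersect, lapply(cs[eff], function(d) d$feature))
  excluded <- unique(unlist(lapply(cs[ineff], function(d) d$feature)))
  cand <- setdiff(cand, excluded)
  if (!length(cand))
    return(data.frame(feature = character(), altitude_preference = character(),
                      support = character(), stringsAsFactors = FALSE))
  rows <- lapply(cand, function(f) {
    up_high <- vapply(eff, function(cmp) {
      d <- cs[[cmp]]
      dir <- d$direction[d$feature == f][1]
      if (is.na(dir) || !dir %in% c("UP_IN_A", "UP_IN_B"))
        stop("missing direction for candidate ", f, " in ", cmp)
      dir == "UP_IN_A"  # group_a is the high-environment group
    }, logical(1))
    pref <- if (all(up_high)) "HIGH" else if (all(!up_high)) "LOW"
            else "INCONSISTENT"
    data.frame(feature = f, altitude_preference = pref,
               support = paste(paste0(eff, "=",
                                      ifelse(up_high, "UP_HIGH", "UP_LOW")),
                               collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Feature-by-comparison membership table
#'
#' Boolean table of DE membership across all six comparisons (UpSet-style
#' input), for features DE in at least one comparison.
#'
#' @inheritParams intersect_effective
#' @return data.frame: `feature` plus one logical column per comparison.
#' @export
membership_table <- function(de_sets, screen) {
  cs <- canonicalize_de_sets(de_sets, screen)
  feats <- sort(unique(unlist(lapply(cs, function(d) d$feature))))
  out <- data.frame(feature = feats, stringsAsFactors = FALSE)
  for (cmp in screen$comparison)
    out[[cmp]] <- feats %in% cs[[cmp]]$feature
  out
}
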