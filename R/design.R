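#' Group label for a breed/environment combination
#'
#' The reciprocal-transplant design crosses two breeds (highland `TIB`,
#' lowland `PX`) with two rearing environments (`HIGH`, `LOW`). The four
#' resulting groups carry the conventional labels: Tibetan chickens reared
#' high (`TC`) or low (`LTC`), and Peng'xian yellow chickens reared high
#' (`HLC`) or low (`LC`).
#'
#' @param breed character vector, each element `"TIB"` or `"PX"`.
#' @param env character vector, each element `"HIGH"` or `"LOW"`.
#' @return character vector of group labels (`TC`, `LTC`, `HLC`, `LC`).
#' @export
group_label <- function(breed, env) {
  stopifnot(all(breed %in% c("TIB", "PX")), all(env %in% c("HIGH", "LOW")))
  ifelse(breed == "TIB",
         ifelse(env == "HIGH", "TC", "LTC"),
         ifelse(env == "HIGH", "HLC", "LC"))
}

#' Build a full-factorial sample design table
#'
#' Generates the 2 breeds x 2 environments x tissues x replicates layout of
#' the transplant experiment, one row per sample.
#'
#' @param tissues character vector of tissue names.
#' @param n_reps replicates per (breed, env, tissue) cell.
#' @return data.frame with columns `sample_id`, `breed`, `env`, `tissue`,
#'   `replicate`, `group`.
#' @export
make_sample_design <- function(tissues = c("heart", "liver", "lung", "brain"),
                               n_reps = 3L) {
  stopifnot(length(tissues) >= 1, n_reps >= 1)
  grid <- expand.grid(replicate = seq_len(n_reps),
                      env = c("HIGH", "LOW"),
                      breed = c("TIB", "PX"),
                      tissue = tissues,
                      stringsAsFactors = FALSE)
  grid$group <- group_label(grid$breed, grid$env)
  grid$sample_id <- sprintf("%s_%s_r%d", grid$group, grid$tissue, grid$replicate)
  design <- grid[, c("sample_id", "breed", "env", "tissue", "replicate", "group")]
  rownames(design) <- NULL
  design
}

#' Validate a sample design table
#'
#' Checks the invariants the downstream screen relies on: unique sample ids,
#' legal factor levels, group labels consistent with (breed, env), and at
#' least two replicates in every (group, tissue) cell present.
#'
#' @param design data.frame as returned by [make_sample_design()].
#' @return the design, invisibly, after validation.
#' @export
validate_design <- function(design) {
  req <- c("sample_id", "breed", "env", "tissue", "replicate", "group")
  missing <- setdiff(req, names(design))
  if (length(missing))
    stop("design is missing columns: ", paste(missing, collapse = ", "))
  if (anyDuplicated(design$sample_id))
    stop("duplicated sample_id in design")
  stopifnot(all(design$breed %in% c("TIB", "PX")),
            all(design$env %in% c("HIGH", "LOW")))
  expect_grp <- group_label(design$breed, design$env)
  if (!all(design$group == expect_grp))
    stop("group labels inconsistent with (breed, env)")
  tab <- table(design$group, design$tissue)
  if (any(tab > 0 & tab < 2)) {
    bad <- which(tab > 0 & tab < 2, arr.ind = TRUE)
    stop("fewer than 2 replicates in cell ",
         rownames(tab)[bad[1, 1]], "/", colnames(tab)[bad[1, 2]])
  }
  invisible(design)
}

#' Read and write design tables
#'
#' Plain TSV with the `SampleDesign` columns.
#'
#' @param design data.frame of sample metadata.
#' @param path file path.
#' @return `read_design` returns the validated design data.frame.
#' @export
write_design <- function(design, path) {
  utils::write.table(design, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  design <- utils::read.table(path, sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE)
  validate_design(design)
  design
}
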