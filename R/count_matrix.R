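#' Construct a paired IP/input count matrix
#'
#' The central data container of the package: an integer gene-by-sample count
#' matrix together with per-sample annotations describing the RiboTag/TRAP
#' design — which fraction each library is (`IP`, affinity-purified
#' ribosome-bound RNA, or `input`, total-tissue RNA), which experimental
#' condition it comes from, and a pair identifier linking each IP library to
#' the input library prepared from the same tissue.
#'
#' @param counts Integer matrix, genes in rows, samples in columns. Row names
#'   are gene identifiers (opaque, case-sensitive strings), column names are
#'   sample identifiers.
#' @param meta Data frame with one row per sample and columns `sample`,
#'   `fraction` (`"IP"` or `"input"`), `condition`, and `pair`. Additional
#'   columns (e.g. `library_size`) are kept.
#' @param conditions Optional character vector giving the condition levels in
#'   their intended order (first level = reference). Defaults to the order of
#'   appearance in `meta`.
#' @return An object of class `count_matrix`: a list with elements `counts`
#'   and `meta` (with `fraction` and `condition` as factors).
#' @examples
#' counts <- matrix(rpois(12, 50), nrow = 3,
#'                  dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' meta <- data.frame(sample = paste0("s", 1:4),
#'                    fraction = c("IP", "input", "IP", "input"),
#'                    condition = c("naive", "naive", "dpi2", "dpi2"),
#'                    pair = c("p1", "p1", "p2", "p2"))
#' cm <- count_matrix(counts, meta)
#' dim(cm)
#' @export
count_matrix <- function(counts, meta, conditions = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    rc_stop("counts must have gene row names and sample column names",
            "riboclean_contract_error")
  }
  if (anyDuplicated(rownames(counts))) {
    rc_stop("duplicate gene identifiers in count matrix",
            "riboclean_contract_error")
  }
  if (anyDuplicated(colnames(counts))) {
    rc_stop("duplicate sample identifiers in count matrix",
            "riboclean_contract_error")
  }
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(abs(counts - round(counts)) > 1e-8)) {
    bad <- which(!is.finite(counts) | counts < 0 |
                   abs(counts - round(counts)) > 1e-8, arr.ind = TRUE)[1, ]
    rc_stop(sprintf("non-integer or negative count for gene '%s', sample '%s'",
                    rownames(counts)[bad[1]], colnames(counts)[bad[2]]),
            "riboclean_parse_error")
  }
  storage.mode(counts) <- "integer"

  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  needed <- c("sample", "fraction", "condition", "pair")
  missing_cols <- setdiff(needed, names(meta))
  if (length(missing_cols)) {
    rc_stop(paste0("metadata is missing column(s): ",
                   paste(missing_cols, collapse = ", ")),
            "riboclean_contract_error")
  }
  if (!setequal(meta$sample, colnames(counts))) {
    extra_meta <- setdiff(meta$sample, colnames(counts))
    extra_counts <- setdiff(colnames(counts), meta$sample)
    rc_stop(paste0(
      "metadata and count matrix samples disagree",
      if (length(extra_meta)) paste0("; only in metadata: ",
                                     paste(extra_meta, collapse = ", ")) else "",
      if (length(extra_counts)) paste0("; only in counts: ",
                                       paste(extra_counts, collapse = ", ")) else ""
    ), "riboclean_contract_error")
  }
  meta <- meta[match(colnames(counts), meta$sample), , drop = FALSE]
  rownames(meta) <- meta$sample

  if (!all(meta$fraction %in% c("IP", "input"))) {
    rc_stop("fraction must be 'IP' or 'input' for every sample",
            "riboclean_contract_error")
  }
  meta$fraction <- factor(meta$fraction, levels = c("input", "IP"))
  if (is.null(conditions)) conditions <- unique(as.character(meta$condition))
  meta$condition <- factor(as.character(meta$condition), levels = conditions)
  if (anyNA(meta$condition)) {
    rc_stop("metadata contains conditions outside the declared level set",
            "riboclean_contract_error")
  }

  # Every IP library must pair with exactly one input library.
  unpaired <- character(0)
  for (i in which(meta$fraction == "IP")) {
    partners <- which(meta$fraction == "input" & meta$pair == meta$pair[i])
    if (length(partners) != 1L) unpaired <- c(unpaired, meta$sample[i])
  }
  if (length(unpaired)) {
    rc_warn(paste0("IP sample(s) without a unique input partner: ",
                   paste(unpaired, collapse = ", ")),
            "riboclean_unpaired_warning")
  }

  structure(list(counts = counts, meta = meta), class = "count_matrix")
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  tab <- table(condition = x$meta$condition, fraction = x$meta$fraction)
  print(tab)
  invisible(x)
}

#' Subset a count matrix by genes and/or samples
#'
#' @param x A `count_matrix`.
#' @param genes Gene identifiers or indices (default: all).
#' @param samples Sample identifiers or a logical vector over samples
#'   (default: all).
#' @param drop_levels Drop unused condition levels (default `FALSE`).
#' @return A `count_matrix` restricted to the selection.
#' @export
subset_counts <- function(x, genes = NULL, samples = NULL, drop_levels = FALSE) {
  stopifnot(inherits(x, "count_matrix"))
  counts <- x$counts
  meta <- x$meta
  if (!is.null(genes)) counts <- counts[genes, , drop = FALSE]
  if (!is.null(samples)) {
    counts <- counts[, samples, drop = FALSE]
    meta <- meta[colnames(counts), , drop = FALSE]
  }
  if (drop_levels) meta$condition <- droplevels(meta$condition)
  structure(list(counts = counts, meta = meta), class = "count_matrix")
}
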