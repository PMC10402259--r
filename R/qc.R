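# Experiment-level quality control: delta-delta-Ct fold-enrichment from
# qPCR marker cards, count-based marker-panel enrichment, and a PCA summary
# of the sample structure.

#' Fold enrichment by the delta-delta-Ct method
#'
#' Computes `2^(-ddCt)` with `ddCt = (Ct_target_IP - Ct_ref_IP) -
#' (Ct_target_input - Ct_ref_input)`. Multiple reference transcripts are
#' combined by averaging their Ct values (arithmetic mean) before
#' differencing. A fold of 4 corresponds to a 2-cycle IP advantage at equal
#' references; adding a constant to all Cts of one sample leaves the fold
#' unchanged.
#'
#' @param ct_target_ip,ct_target_input Target-gene Ct in the IP and input
#'   samples.
#' @param ct_ref_ip,ct_ref_input Reference-gene Ct values (vectors allowed;
#'   averaged).
#' @return Fold enrichment of the target in IP relative to input.
#' @examples
#' ddct_fold(20, c(18, 19), 22, c(18, 19))  # 2 cycles lower in IP -> 4
#' @export
ddct_fold <- function(ct_target_ip, ct_ref_ip, ct_target_input,
                      ct_ref_input) {
  cts <- c(ct_target_ip, ct_ref_ip, ct_target_input, ct_ref_input)
  if (any(!is.finite(cts))) {
    rc_stop("all Ct values must be finite", "riboclean_contract_error")
  }
  ddct <- (ct_target_ip - mean(ct_ref_ip)) -
    (ct_target_input - mean(ct_ref_input))
  2^(-ddct)
}

#' Count-based marker-panel enrichment
#'
#' For each IP/input pair and each marker gene, computes the ratio of RLE
#' normalized counts (plus a pseudo-count of 1) in IP over input, then the
#' per-cell-type median fold across markers and pairs. A cell type with a
#' median fold below 1 is called `depleted`, otherwise `enriched` — the
#' expected pattern for a successful pulldown is enrichment of the tagged
#' type's markers and depletion of all other panels.
#'
#' @param x A [count_matrix()].
#' @param panel Named list: cell type -> marker gene ids.
#' @param size_factors Optional precomputed RLE factors.
#' @return List of class `qc_report`: `per_marker` (marker x pair folds,
#'   long data frame), `per_type` (cell type, median fold, verdict),
#'   `n_missing` (panel genes absent from the matrix).
#' @export
marker_enrichment <- function(x, panel, size_factors = NULL) {
  stopifnot(inherits(x, "count_matrix"))
  if (!length(panel) || is.null(names(panel))) {
    rc_stop("panel must be a named list of marker vectors",
            "riboclean_contract_error")
  }
  norm <- normalized_counts(x, size_factors)
  meta <- x$meta
  ip_idx <- which(meta$fraction == "IP")
  pairs <- lapply(ip_idx, function(i) {
    j <- which(meta$fraction == "input" & meta$pair == meta$pair[i])
    if (length(j) == 1L) c(ip = i, input = j) else NULL
  })
  pairs <- Filter(Negate(is.null), pairs)
  if (!length(pairs)) {
    rc_stop("no complete IP/input pairs in the data",
            "riboclean_contract_error")
  }
  n_missing <- 0L
  rows <- list()
  for (ct in names(panel)) {
    markers <- panel[[ct]]
    present <- markers[markers %in% rownames(norm)]
    miss <- length(markers) - length(present)
    if (miss > 0) {
      n_missing <- n_missing + miss
      rc_warn(sprintf("%d marker(s) of '%s' absent from the count matrix",
                      miss, ct), "riboclean_marker_warning")
    }
    for (g in present) {
      for (pr in pairs) {
        rows[[length(rows) + 1L]] <- data.frame(
          cell_type = ct, marker = g, pair = meta$pair[pr["ip"]],
          condition = as.character(meta$condition[pr["ip"]]),
          fold = (norm[g, pr["ip"]] + 1) / (norm[g, pr["input"]] + 1),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  per_marker <- do.call(rbind, rows)
  per_type <- do.call(rbind, lapply(split(per_marker, per_marker$cell_type),
                                    function(d) {
    data.frame(cell_type = d$cell_type[1],
               median_fold = stats::median(d$fold),
               verdict = ifelse(stats::median(d$fold) < 1, "depleted",
                                "enriched"),
               stringsAsFactors = FALSE)
  }))
  rownames(per_type) <- NULL
  structure(list(per_marker = per_marker, per_type = per_type,
                 n_missing = n_missing), class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Marker-panel IP/input enrichment:\n")
  print(x$per_type, row.names = FALSE)
  if (x$n_missing > 0) cat(sprintf("(%d panel gene(s) missing)\n",
                                   x$n_missing))
  invisible(x)
}

#' PCA summary of sample structure
#'
#' Principal components of the samples from log2(normalized count + 1)
#' values, feature-centered (optionally scaled). Reports variance-explained
#' fractions and the sample coordinates.
#'
#' @param x A [count_matrix()] or numeric matrix (genes x samples).
#' @param size_factors Optional RLE factors (for a `count_matrix`).
#' @param scale. Scale features to unit variance (default `FALSE`).
#' @param n_components Components to return (default all).
#' @return List of class `pca_summary`: `variance_explained` (fractions,
#'   non-increasing, summing to <= 1), `coordinates` (samples x components),
#'   `sdev`.
#' @export
pca_summary <- function(x, size_factors = NULL, scale. = FALSE,
                        n_components = NULL) {
  mat <- if (inherits(x, "count_matrix")) {
    log2(normalized_counts(x, size_factors) + 1)
  } else {
    as.matrix(x)
  }
  if (ncol(mat) < 2L) {
    rc_stop("PCA needs at least two samples", "riboclean_contract_error")
  }
  # Drop zero-variance features (prcomp with scale. would fail on them).
  v <- apply(mat, 1, stats::var)
  mat_use <- mat[v > 0, , drop = FALSE]
  if (nrow(mat_use) == 0L) {
    k <- min(ncol(mat), nrow(mat))
    return(structure(list(
      variance_explained = rep(0, k),
      coordinates = matrix(0, ncol(mat), k,
                           dimnames = list(colnames(mat),
                                           paste0("PC", seq_len(k)))),
      sdev = rep(0, k)), class = "pca_summary"))
  }
  pc <- stats::prcomp(t(mat_use), center = TRUE, scale. = scale.)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  if (!is.null(n_components)) {
    k <- min(n_components, length(ve))
    ve <- ve[seq_len(k)]
    pc$x <- pc$x[, seq_len(k), drop = FALSE]
    pc$sdev <- pc$sdev[seq_len(k)]
  }
  structure(list(variance_explained = ve, coordinates = pc$x,
                 sdev = pc$sdev), class = "pca_summary")
}

#' @export
print.pca_summary <- function(x, ...) {
  k <- min(5, length(x$variance_explained))
  cat("PCA variance explained:",
      paste0(sprintf("PC%d %.1f%%", seq_len(k),
                     100 * x$variance_explained[seq_len(k)]),
             collapse = ", "), "\n")
  invisible(x)
}
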