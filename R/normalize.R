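#' Relative log expression (median-of-ratios) size factors
#'
#' For each sample, the size factor is the median over reference-eligible
#' genes of the ratio of the gene's count to its geometric mean across all
#' samples. Eligible genes are those with nonzero counts in every sample
#' (so the geometric mean is positive). Factors are not rescaled further:
#' multiplying every count by a constant scales every factor by that
#' constant.
#'
#' @param x A [count_matrix()] or a numeric matrix (genes x samples).
#' @return Numeric vector of positive per-sample size factors, named by
#'   sample.
#' @examples
#' m <- matrix(c(10, 20, 30, 20, 40, 60), nrow = 3,
#'             dimnames = list(paste0("g", 1:3), c("a", "b")))
#' rle_size_factors(m)  # b is twice a
#' @export
rle_size_factors <- function(x) {
  counts <- if (inherits(x, "count_matrix")) x$counts else as.matrix(x)
  eligible <- rowSums(counts == 0) == 0
  if (!any(eligible)) {
    rc_stop(paste0("no gene has nonzero counts in every sample; ",
                   "RLE reference undefined (consider a pseudo-reference)"),
            "riboclean_norm_error")
  }
  ref <- exp(rowMeans(log(counts[eligible, , drop = FALSE])))
  sf <- apply(counts[eligible, , drop = FALSE] / ref, 2, stats::median)
  if (any(!is.finite(sf)) || any(sf <= 0)) {
    rc_stop("non-positive size factor computed", "riboclean_norm_error")
  }
  sf
}

#' Remove genes with low total counts
#'
#' Keeps genes whose summed count across all samples is at least `min_total`
#' (default 10, i.e. genes with fewer than 10 counts across samples are
#' excluded). Gene order is preserved.
#'
#' @param x A [count_matrix()].
#' @param min_total Minimum row sum to keep a gene.
#' @return A filtered `count_matrix`.
#' @export
filter_low_counts <- function(x, min_total = 10) {
  stopifnot(inherits(x, "count_matrix"))
  keep <- rowSums(x$counts) >= min_total
  if (!any(keep)) {
    rc_warn("all genes removed by the low-count filter",
            "riboclean_empty_warning")
  }
  subset_counts(x, genes = which(keep))
}

#' Normalized counts
#'
#' Counts divided by their sample's RLE size factor.
#'
#' @param x A [count_matrix()] or matrix.
#' @param size_factors Optional precomputed factors; computed if missing.
#' @return Numeric matrix of normalized counts.
#' @export
normalized_counts <- function(x, size_factors = NULL) {
  counts <- if (inherits(x, "count_matrix")) x$counts else as.matrix(x)
  if (is.null(size_factors)) size_factors <- rle_size_factors(counts)
  sweep(counts, 2, size_factors, "/")
}
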