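# Gene-set overlap statistics: exact hypergeometric tests with
# representation factors, and the resampling z-score used for operon
# (ChIP-seq target set) enrichment.

#' Hypergeometric overlap test with representation factor
#'
#' For two gene sets inside a universe of size `N`, reports the observed
#' overlap `k`, its chance expectation `n1*n2/N`, the representation factor
#' `k / expected` (1 = exactly as expected by chance), and the exact
#' upper-tail hypergeometric p-value `P[K >= k]`.
#'
#' @param set_a,set_b Character vectors of gene ids. Members outside the
#'   universe are dropped with a warning.
#' @param universe Either a character vector of gene ids defining the
#'   universe, or a single integer universe size (in which case the sets are
#'   assumed to already lie inside it).
#' @return List of class `overlap_result`: `N`, `n1`, `n2`, `k`, `expected`,
#'   `representation_factor` (NA when the expectation is 0), `p`,
#'   `overlap_genes` (when the universe is a vector), `n_dropped`.
#' @examples
#' hypergeom_overlap(paste0("g", 1:100), paste0("g", 96:145),
#'                   universe = paste0("g", 1:1000))
#' @export
hypergeom_overlap <- function(set_a, set_b, universe) {
  if (length(universe) == 1L && is.numeric(universe)) {
    N <- as.integer(universe)
    if (N <= 0) {
      rc_stop("universe size must be positive", "riboclean_contract_error")
    }
    a <- unique(set_a)
    b <- unique(set_b)
    n_dropped <- 0L
    overlap_genes <- intersect(a, b)
  } else {
    universe <- unique(as.character(universe))
    N <- length(universe)
    if (N == 0L) {
      rc_stop("empty universe", "riboclean_contract_error")
    }
    a0 <- unique(set_a)
    b0 <- unique(set_b)
    a <- intersect(a0, universe)
    b <- intersect(b0, universe)
    n_dropped <- (length(a0) - length(a)) + (length(b0) - length(b))
    if (n_dropped > 0) {
      rc_warn(sprintf("%d set member(s) outside the universe dropped",
                      n_dropped), "riboclean_universe_warning")
    }
    overlap_genes <- intersect(a, b)
  }
  n1 <- length(a)
  n2 <- length(b)
  k <- length(overlap_genes)
  if (n1 > N || n2 > N) {
    rc_stop("set larger than the universe", "riboclean_contract_error")
  }
  expected <- n1 * n2 / N
  rf <- if (expected > 0) k / expected else NA_real_
  # Upper tail P[K >= k]; at k = 0 this is 1 by convention.
  p <- if (k == 0) 1 else stats::phyper(k - 1, n1, N - n1, n2,
                                        lower.tail = FALSE)
  structure(list(N = N, n1 = n1, n2 = n2, k = k, expected = expected,
                 representation_factor = rf, p = p,
                 overlap_genes = overlap_genes, n_dropped = n_dropped),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf(paste0("overlap: k = %d of n1 = %d x n2 = %d in N = %d\n",
                     "expected %.2f, representation factor %s, p = %.3g\n"),
              x$k, x$n1, x$n2, x$N, x$expected,
              ifelse(is.na(x$representation_factor), "NA",
                     sprintf("%.2f", x$representation_factor)), x$p))
  invisible(x)
}

#' Overlap of a query set against a gene-set collection
#'
#' @param query Character vector of gene ids.
#' @param sets Named list of gene sets (e.g. from [read_gmt()]).
#' @param universe Universe gene vector or size (see [hypergeom_overlap()]).
#' @return Data frame with one row per set: `set`, `N`, `n_query`, `n_set`,
#'   `overlap`, `expected`, `representation_factor`, `p`, `q` (BH across
#'   sets).
#' @export
overlap_table <- function(query, sets, universe) {
  rows <- lapply(names(sets), function(nm) {
    o <- suppressWarnings(hypergeom_overlap(query, sets[[nm]], universe))
    data.frame(set = nm, N = o$N, n_query = o$n1, n_set = o$n2,
               overlap = o$k, expected = o$expected,
               representation_factor = o$representation_factor, p = o$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Resampling z-score for operon (gene-set) overlap specificity
#'
#' Compares the observed overlap of a query gene list with each operon
#' target set against the overlap distribution of random same-size gene sets
#' drawn without replacement from a background of expressed genes:
#' `z = (k_obs - null_mean) / null_sd`, with the null moments estimated over
#' `K` random draws (sample standard deviation, `K - 1` denominator). By
#' default the same `K` random sets are reused across operons so that
#' per-operon z-scores share a null.
#'
#' @param query Character vector (the gene list under test).
#' @param operon_sets Named list of gene sets.
#' @param background Character vector of expressed genes to resample from;
#'   must be at least as large as the query.
#' @param K Number of random sets (default 1000; `small_resample` sets 10).
#' @param seed Integer seed (required; the draw is deterministic given it).
#' @param z_threshold Specificity cutoff for the `pass` flag.
#' @param small_resample Use 10 random sets, reproducing the small-resample
#'   variant of the procedure (its sd is unstable; the default K is
#'   preferred for a usable z > 5 rule).
#' @param share_null Reuse one list of random sets for all operons (default)
#'   or redraw per operon.
#' @return Data frame of class `operon_z_result`: `set`, `n_query`, `n_set`,
#'   `k_obs`, `null_mean`, `null_sd`, `z`, `pass`. `z` is `NA` (flagged
#'   undefined) when `null_sd` is 0.
#' @export
operon_zscore <- function(query, operon_sets, background, K = 1000, seed,
                          z_threshold = 5, small_resample = FALSE,
                          share_null = TRUE) {
  if (small_resample) K <- 10
  if (K < 2) {
    rc_stop("K must be at least 2 (sample sd undefined otherwise)",
            "riboclean_contract_error")
  }
  if (missing(seed) || is.null(seed)) {
    rc_stop("operon_zscore requires an explicit seed",
            "riboclean_config_error")
  }
  query <- unique(query)
  background <- unique(background)
  if (length(background) < length(query)) {
    rc_stop("background smaller than the query set",
            "riboclean_contract_error")
  }
  if (!length(operon_sets) ||
      any(!vapply(operon_sets, length, 1L))) {
    rc_stop("operon sets must be nonempty", "riboclean_contract_error")
  }
  n <- length(query)
  with_seed(seed, {
    draw_sets <- function() {
      replicate(K, sample(background, n), simplify = FALSE)
    }
    shared <- if (share_null) draw_sets() else NULL
    rows <- lapply(names(operon_sets), function(nm) {
      op <- unique(operon_sets[[nm]])
      k_obs <- length(intersect(query, op))
      rand <- if (share_null) shared else draw_sets()
      k_null <- vapply(rand, function(s) length(intersect(s, op)), 1L)
      m <- mean(k_null)
      s <- stats::sd(k_null)
      z <- if (s > 0) (k_obs - m) / s else NA_real_
      data.frame(set = nm, n_query = n, n_set = length(op), k_obs = k_obs,
                 null_mean = m, null_sd = s, z = z,
                 pass = !is.na(z) & z > z_threshold,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    class(out) <- c("operon_z_result", "data.frame")
    out
  })
}
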