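# Synthetic RiboTag experiments: negative binomial counts from a cell-type
# mixture with condition-dependent proportions, cell-type-specific injury
# fold-changes, and IP libraries contaminated by a tunable share of the
# ambient (input) transcript pool.

default_proportions <- function() {
  # Rows: conditions; columns: cell types. Inflammatory expansion after
  # injury: microglia/macrophages surge acutely (dpi2), partially resolve by
  # dpi42; OL and neuron shares shrink correspondingly.
  m <- rbind(
    naive = c(OL = 0.35, microglia = 0.10, astrocyte = 0.25, neuron = 0.30),
    dpi2  = c(OL = 0.20, microglia = 0.45, astrocyte = 0.20, neuron = 0.15),
    dpi10 = c(OL = 0.25, microglia = 0.30, astrocyte = 0.25, neuron = 0.20),
    dpi42 = c(OL = 0.32, microglia = 0.15, astrocyte = 0.25, neuron = 0.28)
  )
  m
}

#' Configure a synthetic RiboTag experiment
#'
#' Defines the generative model: each gene has a baseline expression rate per
#' cell type; tissue composition (cell-type proportions) varies by condition;
#' injury acts through per-gene, per-cell-type, per-condition log2
#' fold-changes. The input (total RNA) library samples the ambient pool
#' \eqn{\sum_t \pi_{t,c}\,\lambda_{g,t}\,2^{\beta_{g,t,c}}}; the IP library
#' samples a convex mixture of the tagged cell type's own pool (weight
#' \eqn{1-c}) and that ambient pool (weight \eqn{c}), modelling non-specific
#' co-purification of abundant off-target transcripts with the beads.
#'
#' @param n_genes Number of genes.
#' @param cell_types Cell type names; the first is the tagged (IP target)
#'   type unless `tagged_cell_type` says otherwise.
#' @param conditions Ordered condition names; the first is the uninjured
#'   reference.
#' @param proportions Condition-by-cell-type matrix of tissue proportions;
#'   each row must sum to 1. Default: a post-injury inflammatory-expansion
#'   scenario over naive/dpi2/dpi10/dpi42.
#' @param n_replicates Replicate pairs (IP + input) per condition.
#' @param baseline_expression Optional genes-by-cell-types matrix of
#'   nonnegative rates. If `NULL`, generated: each gene gets a primary cell
#'   type and a log-normal rate there, with `offtype_leak` times that rate in
#'   the other types.
#' @param injury_lfc Optional genes x cell-types x conditions array of log2
#'   fold-changes. If `NULL`, generated from `frac_ol_de` / `frac_contaminant`.
#' @param contamination_fraction Share `c` of each IP library drawn from the
#'   ambient pool, in `[0, 1)`.
#' @param ip_capture_bias Per-gene multiplicative capture factor for the
#'   tagged cell type (scalar or length `n_genes`).
#' @param dispersion Negative binomial dispersion alpha (Var = mu + alpha
#'   mu^2), scalar or per gene.
#' @param library_size_range Samples' expected totals are drawn log-uniformly
#'   from this interval.
#' @param tagged_cell_type Which cell type the IP captures.
#' @param frac_ol_de Fraction of genes given a true translational response in
#'   the tagged cell type (applied in all injured conditions).
#' @param ol_de_lfc Magnitude of that response in log2 units (sign split
#'   half up, half down).
#' @param frac_contaminant Fraction of genes given an inflammatory surge in
#'   the microglia/macrophage compartment (no change in the tagged type).
#' @param contaminant_lfc Magnitude of the inflammatory surge (log2).
#' @param offtype_leak Relative expression of a gene in its non-primary cell
#'   types.
#' @param primary_type_prob Sampling probabilities of the primary cell type
#'   per gene (same order as `cell_types`).
#' @param de_truth_threshold |log2FC| in the tagged type above which a gene
#'   counts as truly responsive in the truth table.
#' @param seed Integer seed; required (reproducibility contract).
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(n_genes = 2000,
                       cell_types = c("OL", "microglia", "astrocyte", "neuron"),
                       conditions = c("naive", "dpi2", "dpi10", "dpi42"),
                       proportions = NULL,
                       n_replicates = 3,
                       baseline_expression = NULL,
                       injury_lfc = NULL,
                       contamination_fraction = 0.1,
                       ip_capture_bias = 1,
                       dispersion = 0.05,
                       library_size_range = c(5e5, 2e6),
                       tagged_cell_type = cell_types[[1]],
                       frac_ol_de = 0.05,
                       ol_de_lfc = 2,
                       frac_contaminant = 0.05,
                       contaminant_lfc = 3,
                       offtype_leak = 0.05,
                       primary_type_prob = NULL,
                       de_truth_threshold = 1,
                       seed = NULL) {
  if (is.null(seed)) {
    rc_stop("sim_config requires an explicit integer seed",
            "riboclean_config_error")
  }
  if (is.null(proportions)) {
    proportions <- default_proportions()
    proportions <- proportions[conditions, cell_types, drop = FALSE]
  }
  proportions <- as.matrix(proportions)
  if (!identical(sort(rownames(proportions)), sort(conditions)) ||
      !identical(sort(colnames(proportions)), sort(cell_types))) {
    rc_stop("proportions must be a conditions x cell_types matrix with names",
            "riboclean_config_error")
  }
  proportions <- proportions[conditions, cell_types, drop = FALSE]
  if (any(proportions < 0) ||
      any(abs(rowSums(proportions) - 1) > 1e-9)) {
    rc_stop("cell-type proportions must be nonnegative and sum to 1 per condition",
            "riboclean_config_error")
  }
  if (contamination_fraction < 0 || contamination_fraction >= 1) {
    rc_stop("contamination_fraction must lie in [0, 1)",
            "riboclean_config_error")
  }
  if (any(dispersion <= 0)) {
    rc_stop("dispersion must be positive", "riboclean_config_error")
  }
  if (length(library_size_range) != 2L || any(library_size_range <= 0) ||
      diff(library_size_range) < 0) {
    rc_stop("library_size_range must be a positive increasing interval",
            "riboclean_config_error")
  }
  if (!tagged_cell_type %in% cell_types) {
    rc_stop("tagged_cell_type must be one of cell_types",
            "riboclean_config_error")
  }
  if (!is.null(baseline_expression)) {
    baseline_expression <- as.matrix(baseline_expression)
    if (nrow(baseline_expression) != n_genes ||
        ncol(baseline_expression) != length(cell_types)) {
      rc_stop("baseline_expression must be n_genes x length(cell_types)",
              "riboclean_config_error")
    }
    if (any(!is.finite(baseline_expression)) || any(baseline_expression < 0)) {
      rc_stop("baseline_expression rates must be finite and >= 0",
              "riboclean_config_error")
    }
  }
  if (!is.null(injury_lfc)) {
    injury_lfc <- as.array(injury_lfc)
    if (!all(dim(injury_lfc) == c(n_genes, length(cell_types),
                                  length(conditions)))) {
      rc_stop("injury_lfc must be n_genes x cell_types x conditions",
              "riboclean_config_error")
    }
  }
  if (is.null(primary_type_prob)) {
    primary_type_prob <- rep(1 / length(cell_types), length(cell_types))
    # The tagged type hosts a larger share of detected genes in an IP-focused
    # design; bias the assignment toward it.
    primary_type_prob[match(tagged_cell_type, cell_types)] <- 2 / length(cell_types)
    primary_type_prob <- primary_type_prob / sum(primary_type_prob)
  }
  structure(list(
    n_genes = as.integer(n_genes), cell_types = cell_types,
    conditions = conditions, proportions = proportions,
    n_replicates = as.integer(n_replicates),
    baseline_expression = baseline_expression, injury_lfc = injury_lfc,
    contamination_fraction = contamination_fraction,
    ip_capture_bias = ip_capture_bias, dispersion = dispersion,
    library_size_range = library_size_range,
    tagged_cell_type = tagged_cell_type,
    frac_ol_de = frac_ol_de, ol_de_lfc = ol_de_lfc,
    frac_contaminant = frac_contaminant, contaminant_lfc = contaminant_lfc,
    offtype_leak = offtype_leak, primary_type_prob = primary_type_prob,
    de_truth_threshold = de_truth_threshold,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' The default desk-scale scenario
#'
#' 2,000 genes, four cell types, four conditions, three replicate pairs per
#' condition (24 libraries), 10% IP contamination, true tagged-cell-type
#' responses of +/-2 log2 units in 5% of genes and an inflammatory
#' microglial surge (+3 log2) in another 5% — structured like a paired
#' translatome profiling study at a size a laptop handles.
#'
#' @param seed Integer seed.
#' @param ... Overrides passed to [sim_config()].
#' @return A `sim_config`.
#' @export
default_scenario_config <- function(seed, ...) {
  sim_config(seed = seed, ...)
}

# Materialize the gene-level parameters (baseline rates, injury LFCs, primary
# types). Randomness is consumed from the current RNG stream.
realize_params <- function(config) {
  n <- config$n_genes
  ct <- config$cell_types
  cond <- config$conditions
  primary <- sample(ct, n, replace = TRUE, prob = config$primary_type_prob)
  if (is.null(config$baseline_expression)) {
    base <- stats::rlnorm(n, meanlog = 4, sdlog = 1.2)
    expr <- matrix(config$offtype_leak * base, n, length(ct),
                   dimnames = list(NULL, ct))
    expr[cbind(seq_len(n), match(primary, ct))] <- base
  } else {
    expr <- config$baseline_expression
    colnames(expr) <- ct
  }
  if (is.null(config$injury_lfc)) {
    lfc <- array(0, dim = c(n, length(ct), length(cond)),
                 dimnames = list(NULL, ct, cond))
    injured <- cond[-1]
    tagged <- config$tagged_cell_type
    ol_genes <- which(primary == tagged)
    n_de <- min(round(config$frac_ol_de * n), length(ol_genes))
    de_idx <- if (n_de > 0) sample(ol_genes, n_de) else integer(0)
    signs <- rep(c(1, -1), length.out = length(de_idx))
    mg <- if ("microglia" %in% ct) "microglia" else ct[min(2, length(ct))]
    mg_genes <- if (mg == tagged) integer(0) else {
      setdiff(which(primary == mg), de_idx)
    }
    n_cont <- min(round(config$frac_contaminant * n), length(mg_genes))
    cont_idx <- if (n_cont > 0) sample(mg_genes, n_cont) else integer(0)
    for (cd in injured) {
      lfc[de_idx, tagged, cd] <- signs * config$ol_de_lfc
      lfc[cont_idx, mg, cd] <- config$contaminant_lfc
    }
  } else {
    lfc <- config$injury_lfc
    dimnames(lfc) <- list(NULL, ct, cond)
  }
  bias <- rep_len(config$ip_capture_bias, n)
  alpha <- rep_len(config$dispersion, n)
  list(primary = primary, expr = expr, lfc = lfc, bias = bias, alpha = alpha)
}

# Per-condition relative abundances (columns sum to 1) of the tagged-cell
# pool and the ambient pool, plus the IP mixture.
mixture_shares <- function(config, params) {
  ct <- config$cell_types
  cond <- config$conditions
  n <- config$n_genes
  tagged <- config$tagged_cell_type
  cfrac <- config$contamination_fraction
  amb <- ip <- tag <- matrix(0, n, length(cond), dimnames = list(NULL, cond))
  for (cd in cond) {
    rate <- params$expr * 2^params$lfc[, , cd]  # genes x cell types
    ambient <- as.vector(rate %*% config$proportions[cd, ct])
    tag_pool <- rate[, tagged] * params$bias
    amb_share <- ambient / sum(ambient)
    tag_share <- tag_pool / sum(tag_pool)
    amb[, cd] <- amb_share
    tag[, cd] <- tag_share
    ip[, cd] <- (1 - cfrac) * tag_share + cfrac * amb_share
  }
  list(ambient = amb, tagged = tag, ip = ip)
}

#' Analytic expected counts for a simulation configuration
#'
#' Returns, per unit library size, the expected relative abundance of each
#' gene in the IP and input fractions for every condition. Multiplying a
#' column by a library size gives the expected counts of a library from that
#' condition.
#'
#' @param config A [sim_config()].
#' @return List with matrices `ip` and `input` (genes x conditions; columns
#'   sum to 1) and the realized gene parameters (`primary`, `expr`, `lfc`).
#' @export
expected_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  params <- with_seed(config$seed, realize_params(config))
  sh <- mixture_shares(config, params)
  list(ip = sh$ip, input = sh$ambient, primary = params$primary,
       expr = params$expr, lfc = params$lfc)
}

#' Simulate a paired IP/input translatome experiment
#'
#' Draws negative binomial counts for `n_replicates` IP/input pairs per
#' condition from the mixture model described in [sim_config()], and returns
#' the counts together with a ground-truth table for benchmarking the
#' downstream statistics.
#'
#' Truth columns, per gene and injured condition:
#' \describe{
#'   \item{true_de}{|log2FC| in the tagged cell type at or above the truth
#'     threshold — a genuine translational response.}
#'   \item{contaminant_driven}{the ambient (input) pool changed by at least
#'     one log2 unit while the tagged cell type did not change at all — any
#'     apparent IP regulation of such a gene is contamination.}
#'   \item{true_enrichment}{log2 ratio of the gene's share in the tagged pool
#'     to its share in the ambient pool.}
#' }
#'
#' @param config A [sim_config()].
#' @return List with elements `counts` (a [count_matrix()] whose metadata
#'   includes `library_size`), `truth` (data frame, one row per gene x
#'   injured condition, plus `primary_type` and naive enrichment), and
#'   `params` (realized gene-level parameters).
#' @examples
#' sim <- simulate_experiment(sim_config(n_genes = 100, seed = 1))
#' dim(sim$counts)
#' head(sim$truth)
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    params <- realize_params(config)
    sh <- mixture_shares(config, params)
    cond <- config$conditions
    nrep <- config$n_replicates
    n <- config$n_genes
    genes <- sprintf("gene%04d", seq_len(n))

    sample_meta <- expand.grid(rep = seq_len(nrep), condition = cond,
                               fraction = c("input", "IP"),
                               stringsAsFactors = FALSE)
    sample_meta$pair <- paste0(sample_meta$condition, "_r", sample_meta$rep)
    sample_meta$sample <- paste0(sample_meta$pair, "_",
                                 sample_meta$fraction)
    lsr <- log(config$library_size_range)
    sample_meta$library_size <- round(exp(stats::runif(nrow(sample_meta),
                                                       lsr[1], lsr[2])))
    counts <- matrix(0L, n, nrow(sample_meta),
                     dimnames = list(genes, sample_meta$sample))
    for (j in seq_len(nrow(sample_meta))) {
      share <- if (sample_meta$fraction[j] == "IP") {
        sh$ip[, sample_meta$condition[j]]
      } else {
        sh$ambient[, sample_meta$condition[j]]
      }
      mu <- sample_meta$library_size[j] * share
      counts[, j] <- stats::rnbinom(n, mu = mu, size = 1 / params$alpha)
    }
    cm <- count_matrix(counts,
                       sample_meta[, c("sample", "fraction", "condition",
                                       "pair", "library_size")],
                       conditions = cond)

    tagged <- config$tagged_cell_type
    injured <- cond[-1]
    truth <- do.call(rbind, lapply(injured, function(cd) {
      tag_lfc <- params$lfc[, tagged, cd]
      amb_change <- log2(sh$ambient[, cd] / sh$ambient[, cond[1]])
      data.frame(
        gene = genes, condition = cd,
        primary_type = params$primary,
        tagged_lfc = tag_lfc,
        true_de = abs(tag_lfc) >= config$de_truth_threshold,
        ambient_log2_change = amb_change,
        contaminant_driven = (abs(amb_change) >= 1) & (tag_lfc == 0),
        true_enrichment = log2(sh$tagged[, cd] / sh$ambient[, cd]),
        true_enrichment_naive = log2(sh$tagged[, cond[1]] /
                                       sh$ambient[, cond[1]]),
        stringsAsFactors = FALSE
      )
    }))
    rownames(truth) <- NULL
    list(counts = cm, truth = truth, params = params, config = config)
  })
}

#' Derive a cell-type marker panel from simulation truth
#'
#' Picks, per cell type, the genes most specifically expressed there (primary
#' type, no injury response, highest baseline), mimicking curated marker
#' panels used for IP quality control.
#'
#' @param sim Result of [simulate_experiment()].
#' @param n_per_type Markers per cell type.
#' @return Named list of gene id vectors (class `gene_set_collection`).
#' @export
marker_panel_from_truth <- function(sim, n_per_type = 20) {
  params <- sim$params
  genes <- rownames(sim$counts$counts)
  responsive <- apply(params$lfc != 0, 1, any)
  sets <- lapply(sim$config$cell_types, function(ct) {
    idx <- which(params$primary == ct & !responsive)
    idx <- idx[order(params$expr[idx, ct], decreasing = TRUE)]
    genes[utils::head(idx, n_per_type)]
  })
  names(sets) <- sim$config$cell_types
  structure(sets, description = rep("simulated markers", length(sets)),
            class = "gene_set_collection")
}
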