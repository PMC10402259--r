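# IP/input enrichment profiles, the fraction-by-condition interaction
# (differential enrichment), and the two-arm filtration of differential
# expression calls against ambient contamination.

#' Differential expression within one fraction
#'
#' Compares an injured condition to the reference within a single fraction
#' (by default the IP translatome): genes with `|log2fc| > 1, q < 0.05` are
#' the unfiltered candidate responders that the two-arm filter then screens.
#'
#' @param x A [count_matrix()].
#' @param condition Condition to compare against the reference.
#' @param reference Reference condition (default: first level).
#' @param fraction Which fraction to analyze, `"IP"` or `"input"`.
#' @param dispersion Passed to [nb_glm()].
#' @return A `de_result` data frame (see [wald_contrast()]).
#' @export
de_condition <- function(x, condition, reference = levels(x$meta$condition)[1],
                         fraction = "IP", dispersion = "moments") {
  stopifnot(inherits(x, "count_matrix"))
  keep <- x$meta$fraction == fraction &
    x$meta$condition %in% c(reference, condition)
  if (!any(x$meta$fraction == fraction & x$meta$condition == condition)) {
    rc_stop(sprintf("no %s samples in condition '%s'", fraction, condition),
            "riboclean_design_error")
  }
  sub <- subset_counts(x, samples = which(keep))
  sub$meta$condition <- factor(as.character(sub$meta$condition),
                               levels = c(reference, condition))
  fit <- nb_glm(sub, ~ condition, dispersion = dispersion)
  wald_contrast(fit, paste0("condition", condition),
                name = sprintf("%s: %s vs %s", fraction, condition, reference))
}

#' Per-condition IP vs input enrichment
#'
#' Within one condition, contrasts the IP fraction against the paired input
#' fraction; the log2 fold-change is the gene's cell-type enrichment
#' (`Log2FC(Total)` in translatome parlance: positive = enriched on the
#' tagged ribosomes relative to total RNA).
#'
#' @param x A [count_matrix()].
#' @param condition Condition to profile.
#' @param dispersion Passed to [nb_glm()].
#' @param pair_effect Include the pair id as a blocking factor.
#' @return A `de_result` data frame; `log2fc` is the enrichment.
#' @export
condition_enrichment <- function(x, condition, dispersion = "moments",
                                 pair_effect = FALSE) {
  stopifnot(inherits(x, "count_matrix"))
  keep <- x$meta$condition == condition
  if (!all(c("IP", "input") %in% as.character(x$meta$fraction[keep]))) {
    rc_stop(sprintf("condition '%s' lacks one of the fractions", condition),
            "riboclean_design_error")
  }
  sub <- subset_counts(x, samples = which(keep), drop_levels = TRUE)
  fit <- nb_glm(sub, ~ fraction, dispersion = dispersion,
                pair_effect = pair_effect)
  wald_contrast(fit, "fractionIP",
                name = sprintf("enrichment IP/input @ %s", condition))
}

#' Differential enrichment: the fraction x condition interaction
#'
#' Fits the full two-factor model `~ condition + fraction +
#' condition:fraction` on all samples and extracts, per injured condition,
#' the interaction coefficient — the change in IP/input enrichment relative
#' to the reference condition,
#' \deqn{\Delta = \log_2 FC(IP/input)_{SCI} - \log_2 FC(IP/input)_{naive}.}
#' A positive delta means the gene became more enriched on the tagged
#' ribosomes after injury. This is the statistic that separates genuine
#' cell-intrinsic regulation from ambient-pool (contamination) effects: a
#' gene whose IP and input fold-changes are equal has delta ~ 0.
#'
#' @param x A [count_matrix()] containing both fractions in all conditions.
#' @param conditions Injured conditions to report (default: all non-reference
#'   levels).
#' @param test `"wald"` (interaction coefficient) or `"lrt"` (dropping that
#'   coefficient from the full model).
#' @param dispersion Passed to [nb_glm()].
#' @param pair_effect Include the pair id as a blocking factor.
#' @return Data frame of class `interaction_result`: `gene`, `condition`,
#'   `delta` (log2), `se`, `p`, `q` (BH within condition), `flag`.
#' @export
differential_enrichment <- function(x, conditions = NULL,
                                    test = c("wald", "lrt"),
                                    dispersion = "moments",
                                    pair_effect = FALSE) {
  stopifnot(inherits(x, "count_matrix"))
  test <- match.arg(test)
  lev <- levels(x$meta$condition)
  reference <- lev[1]
  if (is.null(conditions)) conditions <- lev[-1]
  tab <- table(x$meta$condition, x$meta$fraction)
  if (any(tab[c(reference, conditions), ] == 0)) {
    rc_stop("every compared condition needs samples in both fractions",
            "riboclean_design_error")
  }
  fit <- nb_glm(x, ~ condition * fraction, dispersion = dispersion,
                pair_effect = pair_effect)
  out <- do.call(rbind, lapply(conditions, function(cd) {
    cf <- paste0("condition", cd, ":fractionIP")
    if (test == "wald") {
      w <- wald_contrast(fit, cf, name = sprintf("delta enrichment %s", cd))
      data.frame(gene = w$gene, condition = cd, delta = w$log2fc, se = w$se,
                 p = w$p, q = w$q, flag = w$flag, stringsAsFactors = FALSE)
    } else {
      red <- fit$design[, setdiff(colnames(fit$design), cf), drop = FALSE]
      l <- lrt_full_vs_reduced(x, fit$design, red,
                               dispersion = fit$dispersion)
      w <- wald_contrast(fit, cf)
      data.frame(gene = l$gene, condition = cd, delta = w$log2fc,
                 se = w$se, p = l$p, q = l$q, flag = l$flag,
                 stringsAsFactors = FALSE)
    }
  }))
  rownames(out) <- NULL
  class(out) <- c("interaction_result", "data.frame")
  out
}

#' Default analysis thresholds
#'
#' The decision thresholds used throughout the filtration:
#' `de_lfc` (|log2FC| for a differential expression call), `enrich_lfc`
#' (enrichment), `high_enrich_lfc` (highly selective expression),
#' `arm2_lfc` (preferential expression required by filtration arm 2),
#' `delta_lfc` (differential enrichment required by arm 1), `q` (FDR), and
#' `z` (resampling specificity). Ties at a threshold pass (inclusive
#' comparisons).
#'
#' @param de_lfc,enrich_lfc,high_enrich_lfc,arm2_lfc,delta_lfc,q,z Overrides.
#' @return Named list.
#' @export
default_thresholds <- function(de_lfc = 1, enrich_lfc = 0.5,
                               high_enrich_lfc = 2, arm2_lfc = 1,
                               delta_lfc = 1, q = 0.05, z = 5) {
  list(de_lfc = de_lfc, enrich_lfc = enrich_lfc,
       high_enrich_lfc = high_enrich_lfc, arm2_lfc = arm2_lfc,
       delta_lfc = delta_lfc, q = q, z = z)
}

#' Classify per-gene enrichment
#'
#' Labels each gene by its IP/input enrichment: `depleted` (log2 enrichment
#' <= -0.5, q < 0.05), `enriched` (>= +0.5, q < 0.05), `highly_selective`
#' (>= +2, q < 0.05, a subset of enriched), otherwise `neutral`. Genes that
#' fail the significance gate are neutral regardless of effect size.
#'
#' @param enrich A `de_result` from [condition_enrichment()].
#' @param thresholds See [default_thresholds()].
#' @return The input with an added ordered factor column `class`
#'   (`depleted < neutral < enriched < highly_selective`); attribute
#'   `class_counts` tabulates the labels.
#' @export
classify_enrichment <- function(enrich, thresholds = default_thresholds()) {
  if (!all(c("log2fc", "q") %in% names(enrich))) {
    rc_stop("enrichment table needs columns log2fc and q",
            "riboclean_contract_error")
  }
  sig <- enrich$q < thresholds$q
  cls <- rep("neutral", nrow(enrich))
  cls[sig & enrich$log2fc <= -thresholds$enrich_lfc] <- "depleted"
  cls[sig & enrich$log2fc >= thresholds$enrich_lfc] <- "enriched"
  cls[sig & enrich$log2fc >= thresholds$high_enrich_lfc] <- "highly_selective"
  enrich$class <- factor(cls, levels = c("depleted", "neutral", "enriched",
                                         "highly_selective"), ordered = TRUE)
  attr(enrich, "class_counts") <- table(enrich$class)
  enrich
}

#' Two-arm contamination filtration of translatome DE calls
#'
#' A differential expression call in the IP fraction is retained as a
#' high-confidence cell-intrinsic response only if it passes one of two
#' arms:
#' \describe{
#'   \item{arm 1}{its IP/input enrichment itself changed after injury, in
#'     the same direction as the expression change (`|delta| >= 1`,
#'     `q < 0.05`, sign agreement) — the change is not mirrored in the
#'     ambient pool;}
#'   \item{arm 2}{the gene is constantly and strongly enriched on the tagged
#'     ribosomes (`log2 enrichment >= 1`, `q < 0.05`, in the reference
#'     condition and in the tested condition) — the tagged cell type is its
#'     major expressor, so even parallel input changes reflect that cell
#'     type.}
#' }
#' `final = de_pass AND (arm1 OR arm2)`. Down-regulated genes are handled
#' with mirrored signs. Ties at thresholds pass.
#'
#' @param de `de_result` for the IP-fraction condition-vs-reference contrast.
#' @param delta [differential_enrichment()] rows for the same condition.
#' @param enrich_ref Classified enrichment profile in the reference
#'   condition ([condition_enrichment()] output).
#' @param enrich_cond Enrichment profile in the tested condition.
#' @param thresholds See [default_thresholds()].
#' @param arm2_mode `"endpoints"` (default): enriched in the reference and
#'   the tested condition; `"all"`: additionally require enrichment in every
#'   profile supplied via `enrich_all`.
#' @param enrich_all Optional named list of enrichment profiles for all
#'   conditions (required for `arm2_mode = "all"`).
#' @return Data frame of class `filtration_report`: `gene`, `condition`,
#'   `log2fc`, `q_de`, `delta`, `q_delta`, `log2_enrich_naive`,
#'   `log2_enrich_cond`, `de_pass`, `arm1`, `arm2`, `final`, `direction`.
#'   Attribute `summary` holds per-arm counts.
#' @export
two_arm_filter <- function(de, delta, enrich_ref, enrich_cond,
                           thresholds = default_thresholds(),
                           arm2_mode = c("endpoints", "all"),
                           enrich_all = NULL) {
  arm2_mode <- match.arg(arm2_mode)
  universe <- de$gene
  for (nm in list(delta = delta, enrich_ref = enrich_ref,
                  enrich_cond = enrich_cond)) {
    if (!setequal(nm$gene, universe)) {
      off <- c(setdiff(nm$gene, universe), setdiff(universe, nm$gene))
      rc_stop(paste0("inputs cover different gene universes; e.g.: ",
                     paste(utils::head(off, 5), collapse = ", ")),
              "riboclean_contract_error")
    }
  }
  delta <- delta[match(universe, delta$gene), ]
  enrich_ref <- enrich_ref[match(universe, enrich_ref$gene), ]
  enrich_cond <- enrich_cond[match(universe, enrich_cond$gene), ]

  q_thr <- thresholds$q
  de_pass <- abs(de$log2fc) >= thresholds$de_lfc & de$q < q_thr
  direction <- ifelse(de$log2fc >= 0, "up", "down")

  arm1 <- abs(delta$delta) >= thresholds$delta_lfc & delta$q < q_thr &
    sign(delta$delta) == sign(de$log2fc)

  enriched_at <- function(e) {
    e$log2fc >= thresholds$arm2_lfc & e$q < q_thr
  }
  arm2 <- enriched_at(enrich_ref) & enriched_at(enrich_cond)
  if (arm2_mode == "all") {
    if (is.null(enrich_all)) {
      rc_stop("arm2_mode = \"all\" needs enrich_all profiles",
              "riboclean_contract_error")
    }
    for (e in enrich_all) {
      e <- e[match(universe, e$gene), ]
      arm2 <- arm2 & enriched_at(e)
    }
  }
  final <- de_pass & (arm1 | arm2)
  cond_label <- if (!is.null(delta$condition)) delta$condition[1] else NA
  out <- data.frame(
    gene = universe,
    condition = cond_label,
    log2fc = de$log2fc, q_de = de$q,
    delta = delta$delta, q_delta = delta$q,
    log2_enrich_naive = enrich_ref$log2fc,
    log2_enrich_cond = enrich_cond$log2fc,
    de_pass = de_pass, arm1 = arm1, arm2 = arm2, final = final,
    direction = direction,
    stringsAsFactors = FALSE, row.names = NULL
  )
  attr(out, "summary") <- c(
    n_genes = length(universe), n_de = sum(de_pass),
    n_arm1 = sum(de_pass & arm1), n_arm2 = sum(de_pass & arm2),
    n_final = sum(final)
  )
  attr(out, "thresholds") <- thresholds
  class(out) <- c("filtration_report", "data.frame")
  out
}

#' @export
print.filtration_report <- function(x, ...) {
  s <- attr(x, "summary")
  cat(sprintf(paste0("two-arm filtration (%s): %d genes; DE %d; ",
                     "arm1 %d; arm2 %d; final %d\n"),
              x$condition[1], s["n_genes"], s["n_de"], s["n_arm1"],
              s["n_arm2"], s["n_final"]))
  invisible(x)
}

#' Acutely specific responders
#'
#' Among genes that pass the up-direction filtration acutely (e.g. dpi2),
#' select those whose late (e.g. dpi42) behavior indicates normalization:
#' either not significantly upregulated late, or at least two-fold lower
#' than the acute response (`log2fc_late <= log2fc_acute - 1`).
#'
#' @param filtered_acute `filtration_report` for the acute condition.
#' @param de_acute,de_late `de_result` tables for the two conditions.
#' @param thresholds See [default_thresholds()].
#' @return Character vector of gene ids.
#' @export
acute_specific_set <- function(filtered_acute, de_acute, de_late,
                               thresholds = default_thresholds()) {
  up <- filtered_acute$gene[filtered_acute$final &
                              filtered_acute$direction == "up"]
  acute <- de_acute[match(up, de_acute$gene), ]
  late <- de_late[match(up, de_late$gene), ]
  not_sig_up_late <- !(late$q < thresholds$q &
                         late$log2fc >= thresholds$de_lfc)
  twofold_lower <- late$log2fc <= acute$log2fc - 1
  up[not_sig_up_late | twofold_lower]
}
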