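# End-to-end pipeline: simulate (or load) -> QC -> normalization/DE ->
# enrichment -> two-arm filtration -> marker overlaps -> operon z-scores,
# driven by one configuration and one root seed.

# Polynomial rolling hash of a string (31-bit); used for the provenance
# record only, not for security.
config_hash <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 7
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Assemble a pipeline run configuration
#'
#' @param out Output directory (created if absent).
#' @param seed Root integer seed; all stage seeds are derived from it.
#' @param counts,meta Optional paths to a count TSV and metadata TSV; when
#'   absent, the synthetic default scenario is generated.
#' @param sim Named list of overrides for [sim_config()] in simulation mode.
#' @param markers,operons Optional GMT paths for the marker panel and operon
#'   target sets; in simulation mode, defaults derived from the simulation
#'   truth are used when these are absent.
#' @param thresholds See [default_thresholds()].
#' @param min_total Low-count filter threshold.
#' @param K Random sets for the operon z-score.
#' @param arm2_mode Passed to [two_arm_filter()].
#' @return Named list of class `run_config`.
#' @export
run_config <- function(out, seed, counts = NULL, meta = NULL, sim = list(),
                       markers = NULL, operons = NULL,
                       thresholds = default_thresholds(), min_total = 10,
                       K = 1000, arm2_mode = "endpoints") {
  if (missing(out) || missing(seed)) {
    rc_stop("run_config requires an output directory and a seed",
            "riboclean_config_error")
  }
  thr <- utils::modifyList(default_thresholds(), thresholds)
  if (thr$q <= 0 || thr$q >= 1) {
    rc_stop("q threshold must lie in (0,1)", "riboclean_config_error")
  }
  if (any(unlist(thr[c("de_lfc", "enrich_lfc", "high_enrich_lfc",
                       "arm2_lfc", "delta_lfc", "z")]) <= 0)) {
    rc_stop("effect-size thresholds must be positive",
            "riboclean_config_error")
  }
  for (p in c(counts, meta, markers, operons)) {
    if (!is.null(p) && !file.exists(p)) {
      rc_stop(paste0("configured input does not exist: ", p),
              "riboclean_config_error")
    }
  }
  structure(list(out = out, seed = as.integer(seed), counts = counts,
                 meta = meta, sim = sim, markers = markers,
                 operons = operons, thresholds = thr,
                 min_total = min_total, K = K, arm2_mode = arm2_mode),
            class = "run_config")
}

log_line <- function(con, stage, msg) {
  line <- sprintf("[%s] %s", stage, msg)
  writeLines(line, con)
  message(line)
}

#' Run the full translatome analysis pipeline
#'
#' Executes every stage on either supplied count data or the synthetic
#' default scenario, writes each stage's output as TSV into the configured
#' directory, and returns the per-condition summary. The run is a pure
#' function of the configuration and the root seed: repeated invocations
#' write byte-identical outputs.
#'
#' Outputs: `counts.tsv`/`samples.tsv`/`truth.tsv` (simulation mode),
#' `qc_report.tsv`, `pca.tsv`, `de_<cond>.tsv`, `enrich_<cond>.tsv`,
#' `delta.tsv`, `filtration.tsv`, `overlap.tsv`, `operon_z.tsv`,
#' `summary.tsv`, `run_config.yaml`, `log.txt`.
#'
#' @param config A [run_config()] or the path of a YAML file with its
#'   fields.
#' @return Invisibly, a list with the summary data frame, the filtration
#'   table and the output directory.
#' @export
run_all <- function(config) {
  if (is.character(config)) {
    cfg <- read_run_config(config)
    config <- do.call(run_config, cfg)
  }
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
  logf <- file(file.path(config$out, "log.txt"), open = "wt")
  on.exit(close(logf), add = TRUE)
  t0 <- Sys.time()

  cfg_echo <- config
  cfg_echo$thresholds <- unclass(cfg_echo$thresholds)
  cfg_yaml <- yaml::as.yaml(unclass(cfg_echo))
  provenance <- list(config_hash = config_hash(cfg_yaml), seed = config$seed,
                     version = as.character(utils::packageVersion("riboclean")))
  writeLines(c(cfg_yaml, "provenance:",
               sprintf("  config_hash: %s", provenance$config_hash),
               sprintf("  seed: %d", provenance$seed),
               sprintf("  version: %s", provenance$version)),
             file.path(config$out, "run_config.yaml"))
  log_line(logf, "start", sprintf("config hash %s, seed %d",
                                  provenance$config_hash, config$seed))

  # Stage 1: data
  sim <- NULL
  if (is.null(config$counts)) {
    sim_args <- utils::modifyList(list(seed = derive_seed(config$seed, 1)),
                                  config$sim)
    sim <- simulate_experiment(do.call(sim_config, sim_args))
    cm <- sim$counts
    write_counts(cm, file.path(config$out, "counts.tsv"),
                 file.path(config$out, "samples.tsv"))
    write_result_tsv(sim$truth, file.path(config$out, "truth.tsv"))
    log_line(logf, "simulate", sprintf("%d genes, %d samples (seed %d)",
                                       nrow(cm$counts), ncol(cm$counts),
                                       derive_seed(config$seed, 1)))
  } else {
    cm <- read_counts(config$counts, config$meta)
    log_line(logf, "load", sprintf("%d genes, %d samples from %s",
                                   nrow(cm$counts), ncol(cm$counts),
                                   config$counts))
  }
  conditions <- levels(cm$meta$condition)
  reference <- conditions[1]
  injured <- conditions[-1]

  # Stage 2: QC
  panel <- if (!is.null(config$markers)) {
    read_gmt(config$markers)
  } else if (!is.null(sim)) {
    marker_panel_from_truth(sim)
  } else {
    NULL
  }
  if (!is.null(panel)) {
    qc <- suppressWarnings(marker_enrichment(cm, panel))
    write_result_tsv(qc$per_type, file.path(config$out, "qc_report.tsv"))
    log_line(logf, "qc", paste(sprintf("%s:%s", qc$per_type$cell_type,
                                       qc$per_type$verdict), collapse = " "))
  }
  pca <- pca_summary(cm)
  write_result_tsv(
    data.frame(sample = rownames(pca$coordinates),
               round(pca$coordinates[, seq_len(min(5, ncol(pca$coordinates))),
                                     drop = FALSE], 6),
               check.names = FALSE),
    file.path(config$out, "pca.tsv"))
  log_line(logf, "pca", sprintf("PC1 %.1f%%, PC2 %.1f%%",
                                100 * pca$variance_explained[1],
                                100 * pca$variance_explained[2]))

  # Stage 3: filter + normalize
  cmf <- filter_low_counts(cm, config$min_total)
  sf <- rle_size_factors(cmf)
  log_line(logf, "normalize",
           sprintf("%d/%d genes pass min_total=%d; size factors %.3g-%.3g",
                   nrow(cmf$counts), nrow(cm$counts), config$min_total,
                   min(sf), max(sf)))

  # Stage 4: DE, enrichment, differential enrichment
  thr <- config$thresholds
  de <- lapply(injured, function(cd) de_condition(cmf, cd))
  names(de) <- injured
  enr <- lapply(conditions, function(cd) {
    classify_enrichment(condition_enrichment(cmf, cd), thr)
  })
  names(enr) <- conditions
  delta <- differential_enrichment(cmf)
  for (cd in injured) {
    write_result_tsv(de[[cd]], file.path(config$out,
                                         sprintf("de_%s.tsv", cd)))
  }
  for (cd in conditions) {
    write_result_tsv(enr[[cd]], file.path(config$out,
                                          sprintf("enrich_%s.tsv", cd)))
  }
  write_result_tsv(delta, file.path(config$out, "delta.tsv"))
  log_line(logf, "de", paste(sprintf("%s:%d DE", injured, vapply(
    de, function(d) sum(abs(d$log2fc) >= thr$de_lfc & d$q < thr$q), 1L
  )), collapse = " "))

  # Stage 5: two-arm filtration
  filt <- lapply(injured, function(cd) {
    two_arm_filter(de[[cd]], delta[delta$condition == cd, ],
                   enr[[reference]], enr[[cd]], thr,
                   arm2_mode = config$arm2_mode, enrich_all = enr)
  })
  names(filt) <- injured
  filt_all <- do.call(rbind, filt)
  write_result_tsv(filt_all, file.path(config$out, "filtration.tsv"))
  summary_df <- do.call(rbind, lapply(injured, function(cd) {
    s <- attr(filt[[cd]], "summary")
    data.frame(condition = cd, n_genes = s["n_genes"], n_de = s["n_de"],
               n_arm1 = s["n_arm1"], n_arm2 = s["n_arm2"],
               n_final = s["n_final"], row.names = NULL)
  }))
  write_result_tsv(summary_df, file.path(config$out, "summary.tsv"))
  for (cd in injured) {
    s <- attr(filt[[cd]], "summary")
    log_line(logf, "filter", sprintf("%s: DE %d -> arm1 %d, arm2 %d, final %d",
                                     cd, s["n_de"], s["n_arm1"], s["n_arm2"],
                                     s["n_final"]))
  }

  # Stage 6: marker overlaps of the up-regulated (unfiltered and filtered)
  universe <- de[[1]]$gene
  if (!is.null(panel)) {
    ov <- do.call(rbind, lapply(injured, function(cd) {
      up_unf <- de[[cd]]$gene[de[[cd]]$log2fc >= thr$de_lfc &
                                de[[cd]]$q < thr$q]
      up_fin <- filt[[cd]]$gene[filt[[cd]]$final &
                                  filt[[cd]]$direction == "up"]
      rbind(
        cbind(condition = cd, stage = "unfiltered",
              overlap_table(up_unf, panel, universe)),
        cbind(condition = cd, stage = "filtered",
              overlap_table(up_fin, panel, universe))
      )
    }))
    write_result_tsv(ov, file.path(config$out, "overlap.tsv"))
    log_line(logf, "overlap", sprintf("%d set x condition tests", nrow(ov)))
  }

  # Stage 7: operon z-scores on the acute up-regulated set
  operons <- if (!is.null(config$operons)) {
    read_gmt(config$operons)
  } else if (!is.null(sim)) {
    # Synthetic stand-ins: one set concentrated in the true responders (a
    # silencing-factor-like target set) and one uniform draw.
    truth1 <- sim$truth[sim$truth$condition == injured[1], ]
    true_up <- truth1$gene[truth1$true_de & truth1$tagged_lfc > 0]
    with_seed(derive_seed(config$seed, 3), {
      list(
        synthetic_responder_targets = unique(c(
          true_up, sample(universe, max(10, length(true_up))))),
        synthetic_random_targets = sample(universe,
                                          max(20, 2 * length(true_up)))
      )
    })
  } else {
    NULL
  }
  if (!is.null(operons)) {
    acute <- injured[1]
    query <- filt[[acute]]$gene[filt[[acute]]$final &
                                  filt[[acute]]$direction == "up"]
    if (length(query) >= 2) {
      oz <- operon_zscore(query, operons, background = universe,
                          K = config$K, seed = derive_seed(config$seed, 4),
                          z_threshold = thr$z)
      write_result_tsv(oz, file.path(config$out, "operon_z.tsv"))
      log_line(logf, "operon-z",
               paste(sprintf("%s z=%.2f", oz$set, oz$z), collapse = " "))
    } else {
      log_line(logf, "operon-z", "skipped: fewer than 2 query genes")
    }
  }

  log_line(logf, "done", sprintf("%.1f s elapsed",
                                 as.numeric(difftime(Sys.time(), t0,
                                                     units = "secs"))))
  invisible(list(summary = summary_df, filtration = filt_all,
                 out = config$out))
}
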