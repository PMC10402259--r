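# On-disk formats. TSV (tab-separated, UTF-8, '.' decimal) is the canonical
# table dialect; GMT for gene sets; YAML for configuration.

#' Read a count matrix and its sample metadata
#'
#' @param path TSV file: first column `gene`, one column per sample, integer
#'   counts.
#' @param meta_path TSV file with columns `sample`, `fraction`, `condition`,
#'   `pair` (extra columns preserved).
#' @param conditions Optional ordered condition levels (first = reference).
#' @return A [count_matrix()].
#' @export
read_counts <- function(path, meta_path, conditions = NULL) {
  for (p in c(path, meta_path)) {
    if (!file.exists(p)) {
      rc_stop(paste0("file not found: ", p), "riboclean_io_error")
    }
  }
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) {
    rc_stop("count table needs a gene column plus at least one sample column",
            "riboclean_parse_error")
  }
  genes <- as.character(tab[[1]])
  mat <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(mat)) {
    bad <- which(is.na(suppressWarnings(apply(tab[, -1, drop = FALSE], 2,
                                              as.numeric))), arr.ind = TRUE)
    where <- if (length(bad)) {
      sprintf(" (gene '%s', sample '%s')", genes[bad[1]],
              colnames(tab)[-1][bad[2]])
    } else ""
    rc_stop(paste0("non-numeric count value", where), "riboclean_parse_error")
  }
  rownames(mat) <- genes
  meta <- utils::read.delim(meta_path, header = TRUE, sep = "\t",
                            check.names = FALSE, stringsAsFactors = FALSE)
  count_matrix(mat, meta, conditions = conditions)
}

#' Write a count matrix and its metadata as TSV
#'
#' Inverse of [read_counts()]: `read_counts(write_counts(cm, ...))` returns an
#' identical object.
#'
#' @param x A `count_matrix`.
#' @param path Output TSV for counts.
#' @param meta_path Output TSV for metadata.
#' @return Invisibly, `c(path, meta_path)`.
#' @export
write_counts <- function(x, path, meta_path) {
  stopifnot(inherits(x, "count_matrix"))
  tab <- data.frame(gene = rownames(x$counts), x$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- x$meta
  meta$fraction <- as.character(meta$fraction)
  meta$condition <- as.character(meta$condition)
  utils::write.table(meta, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(path, meta_path))
}

#' Read gene sets from a GMT file
#'
#' GMT dialect: one set per line, `name TAB description TAB member...`.
#' Duplicate members within a set are removed with a warning.
#'
#' @param path GMT file.
#' @return A named list of character vectors with attribute `description`;
#'   class `gene_set_collection`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) {
    rc_stop(paste0("file not found: ", path), "riboclean_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  descs <- character(0)
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L) {
      rc_stop(sprintf("GMT line %d has fewer than 3 fields", i),
              "riboclean_parse_error")
    }
    name <- fields[[1]]
    members <- fields[-(1:2)]
    members <- members[nzchar(members)]
    if (anyDuplicated(members)) {
      rc_warn(sprintf("set '%s': %d duplicate member(s) removed", name,
                      sum(duplicated(members))), "riboclean_dedup_warning")
      members <- unique(members)
    }
    if (name %in% names(sets)) {
      rc_stop(sprintf("duplicate set name '%s' in GMT", name),
              "riboclean_parse_error")
    }
    sets[[name]] <- members
    descs[name] <- fields[[2]]
  }
  structure(sets, description = descs, class = "gene_set_collection")
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors (or `gene_set_collection`).
#' @param path Output file.
#' @param description Optional per-set description (recycled; default `"."`).
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(sets, path, description = NULL) {
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    rc_stop("all gene sets must be named", "riboclean_contract_error")
  }
  if (is.null(description)) {
    description <- attr(sets, "description")
    if (is.null(description)) description <- rep(".", length(sets))
  }
  description <- rep_len(description, length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a result table as TSV
#'
#' @param x Data frame.
#' @param path Output TSV.
#' @return Invisibly, `path`.
#' @export
write_result_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a result table written by [write_result_tsv()]
#' @param path TSV path.
#' @return Data frame.
#' @export
read_result_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file.
#' @return `read_run_config`: a named list. `write_run_config`: invisibly,
#'   the path.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    rc_stop(paste0("file not found: ", path), "riboclean_io_error")
  }
  yaml::read_yaml(path)
}

#' @rdname read_run_config
#' @param config Named list of configuration values.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
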