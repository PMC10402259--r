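# Per-gene negative binomial generalized linear models with a log link and
# size-factor offsets — the count-level statistical engine behind every
# differential expression and differential enrichment contrast in the
# package. Fitting is by iteratively reweighted least squares at a per-gene
# dispersion estimated by method of moments on normalized counts.

# Build a design matrix from a formula and the sample metadata.
build_design <- function(design, meta) {
  if (inherits(design, "formula")) {
    X <- stats::model.matrix(design, data = meta)
  } else {
    X <- as.matrix(design)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    rc_stop(paste0("design matrix is not full rank; aliased column(s): ",
                   paste(aliased, collapse = ", ")),
            "riboclean_design_error")
  }
  X
}

# Method-of-moments dispersion per gene: within-group variance of RLE
# normalized counts, corrected for the Poisson (shot-noise) component, on
# the groups defined by the unique design rows. Var(K) = mu + alpha mu^2
# implies, on normalized counts y = K/s, E var(y) ~ xim*mu + alpha*mu^2 with
# xim = mean(1/s) (DESeq's classic estimator). Floored at `floor_at`.
#
# With `shrink = TRUE` (the default used by nb_glm), a mean-dispersion
# trend a0 + a1/mu is fitted across genes and each gene takes the maximum
# of its own estimate and the trend ("maximum" sharing). At the replicate
# numbers typical of these designs (n = 3 per group) the raw per-gene
# estimate is so noisy that roughly half the genes land at the floor and
# are tested as if Poisson, which makes the Wald test anti-conservative;
# taking the maximum restores near-nominal type-I error at the cost of a
# little power on genuinely low-dispersion genes.
estimate_dispersion_mom <- function(counts, X, size_factors,
                                    floor_at = 1e-8, fallback = 0.1,
                                    shrink = TRUE) {
  groups <- apply(X, 1, paste, collapse = "\r")
  y <- sweep(counts, 2, size_factors, "/")
  xim <- mean(1 / size_factors)
  grp <- split(seq_len(ncol(counts)), groups)
  grp <- grp[vapply(grp, length, 1L) >= 2L]
  if (length(grp) == 0L) {
    return(rep(fallback, nrow(counts)))
  }
  num <- matrix(0, nrow(counts), length(grp))
  mu_w <- matrix(0, nrow(counts), length(grp))
  dfree <- 0
  for (k in seq_along(grp)) {
    cols <- grp[[k]]
    m <- rowMeans(y[, cols, drop = FALSE])
    v <- apply(y[, cols, drop = FALSE], 1, stats::var)
    num[, k] <- (length(cols) - 1L) * v
    mu_w[, k] <- m
    dfree <- dfree + length(cols) - 1L
  }
  s2 <- rowSums(num) / dfree
  mu_bar <- rowMeans(mu_w)
  alpha_raw <- (s2 - xim * mu_bar) / mu_bar^2
  alpha_raw[!is.finite(alpha_raw)] <- fallback
  alpha <- pmax(alpha_raw, floor_at)
  if (!shrink) return(alpha)
  ok <- alpha_raw > 0 & mu_bar > 0
  trend <- if (sum(ok) >= 10) {
    co <- stats::coef(stats::lm(alpha_raw[ok] ~ I(1 / mu_bar[ok])))
    a0 <- max(co[1], floor_at)
    a1 <- max(co[2], 0)
    a0 + a1 / pmax(mu_bar, 1e-8)
  } else if (any(ok)) {
    rep(stats::median(alpha_raw[ok]), length(alpha))
  } else {
    rep(fallback, length(alpha))
  }
  pmax(alpha, trend)
}

# IRLS fit of one NB GLM: y ~ NB(mu, size = 1/alpha), log mu = X beta + o.
nb_irls_one <- function(y, X, offset, alpha, max_iter = 100, tol = 1e-10) {
  p <- ncol(X)
  eta <- log(pmax(y, 0.5)) - offset
  beta <- tryCatch(qr.solve(X, eta), error = function(e) rep(0, p))
  eta <- drop(X %*% beta) + offset
  eta <- pmin(pmax(eta, -30), 30)
  mu <- exp(eta)
  ll_old <- -Inf
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    w <- mu / (1 + alpha * mu)
    z <- (eta - offset) + (y - mu) / mu
    XtW <- t(X * w)
    beta_new <- tryCatch(solve(XtW %*% X, XtW %*% z),
                         error = function(e) NULL)
    if (is.null(beta_new)) break
    beta <- drop(beta_new)
    eta <- pmin(pmax(drop(X %*% beta) + offset, -30), 30)
    mu <- exp(eta)
    ll <- sum(stats::dnbinom(y, size = 1 / alpha, mu = mu, log = TRUE))
    if (is.finite(ll) && abs(ll - ll_old) < tol * (abs(ll) + 1)) {
      converged <- TRUE
      ll_old <- ll
      break
    }
    ll_old <- ll
  }
  w <- mu / (1 + alpha * mu)
  info <- t(X * w) %*% X
  cov <- tryCatch(solve(info), error = function(e) matrix(NA_real_, p, p))
  list(beta = beta, cov = cov, mu = mu, ll = ll_old, converged = converged)
}

#' Fit per-gene negative binomial GLMs
#'
#' Fits, for every gene, a negative binomial generalized linear model with a
#' log link and the log RLE size factors as offsets:
#' \deqn{K_{gj} \sim NB(\mu_{gj}, \alpha_g), \qquad
#'       \log \mu_{gj} = o_j + x_j^\top \beta_g.}
#' Coefficients are reported on the log2 scale (as fold-change analyses in
#' this field conventionally are); fitting is on the natural-log scale.
#'
#' @param x A [count_matrix()], or a plain counts matrix if `meta` supplies
#'   the sample data.
#' @param design A model formula over the metadata columns (e.g.
#'   `~ condition * fraction`) or a design matrix.
#' @param meta Optional data frame of sample covariates (defaults to the
#'   `count_matrix` metadata).
#' @param size_factors Optional per-sample size factors; RLE factors are
#'   computed when missing.
#' @param dispersion Either `"moments"` (per-gene method-of-moments on
#'   normalized counts, floored at 1e-8, shared with a fitted mean-dispersion
#'   trend by taking the per-gene maximum), `"moments-raw"` (the same without
#'   trend sharing), or a numeric vector of fixed per-gene dispersions. The
#'   default trend sharing keeps the Wald test near its nominal level at
#'   small replicate numbers.
#' @param pair_effect Add the pair identifier as a blocking fixed effect
#'   (only with a formula design).
#' @return An object of class `nbglm` with per-gene coefficients, covariance
#'   matrices, dispersions, log-likelihoods and convergence flags. Methods:
#'   `print`, `summary`, `coef`, `fitted`, `residuals`, `logLik`.
#' @seealso [wald_contrast()], [lrt_full_vs_reduced()]
#' @export
nb_glm <- function(x, design, meta = NULL, size_factors = NULL,
                   dispersion = "moments", pair_effect = FALSE) {
  if (inherits(x, "count_matrix")) {
    counts <- x$counts
    if (is.null(meta)) meta <- x$meta
  } else {
    counts <- as.matrix(x)
    if (is.null(meta)) meta <- data.frame(row.names = colnames(counts))
  }
  if (pair_effect && inherits(design, "formula")) {
    design <- stats::update(design, ~ . + pair)
  }
  X <- build_design(design, meta)
  if (nrow(X) != ncol(counts)) {
    rc_stop("design rows must match the number of samples",
            "riboclean_design_error")
  }
  if (is.null(size_factors)) size_factors <- rle_size_factors(counts)
  offset <- log(size_factors)

  if (is.character(dispersion) && dispersion %in% c("moments",
                                                    "moments-raw")) {
    alpha <- estimate_dispersion_mom(counts, X, size_factors,
                                     shrink = dispersion == "moments")
  } else if (is.numeric(dispersion)) {
    alpha <- pmax(rep_len(dispersion, nrow(counts)), 1e-8)
  } else {
    rc_stop("dispersion must be \"moments\" or a numeric vector",
            "riboclean_config_error")
  }

  n_genes <- nrow(counts)
  p <- ncol(X)
  beta <- matrix(NA_real_, n_genes, p, dimnames = list(rownames(counts),
                                                       colnames(X)))
  covs <- array(NA_real_, dim = c(n_genes, p, p),
                dimnames = list(rownames(counts), colnames(X), colnames(X)))
  ll <- numeric(n_genes)
  converged <- logical(n_genes)
  mu_hat <- matrix(NA_real_, n_genes, ncol(counts),
                   dimnames = dimnames(counts))
  for (g in seq_len(n_genes)) {
    fit <- nb_irls_one(as.numeric(counts[g, ]), X, offset, alpha[g])
    beta[g, ] <- fit$beta
    covs[g, , ] <- fit$cov
    ll[g] <- fit$ll
    converged[g] <- fit$converged
    mu_hat[g, ] <- fit$mu
  }
  if (any(!converged)) {
    rc_warn(sprintf("%d gene model(s) did not converge (flagged, not fatal)",
                    sum(!converged)), "riboclean_convergence_warning")
  }
  structure(list(
    beta = beta, cov = covs, dispersion = alpha, logLik = ll,
    converged = converged, fitted = mu_hat,
    design = X, size_factors = size_factors, counts = counts,
    mean_norm_count = rowMeans(sweep(counts, 2, size_factors, "/"))
  ), class = "nbglm")
}

#' @export
print.nbglm <- function(x, ...) {
  cat(sprintf("nbglm: %d genes, %d samples, %d coefficients\n",
              nrow(x$beta), ncol(x$counts), ncol(x$beta)))
  cat("coefficients:", paste(colnames(x$beta), collapse = ", "), "\n")
  cat(sprintf("converged: %d/%d; median dispersion %.4g\n",
              sum(x$converged), length(x$converged),
              stats::median(x$dispersion)))
  invisible(x)
}

#' @export
summary.nbglm <- function(object, ...) {
  est_log2 <- object$beta / log(2)
  out <- list(
    n_genes = nrow(object$beta),
    coefficients = colnames(object$beta),
    log2_coef_quartiles = apply(est_log2, 2, stats::quantile,
                                probs = c(0.25, 0.5, 0.75)),
    dispersion_summary = summary(object$dispersion),
    n_converged = sum(object$converged)
  )
  class(out) <- "summary.nbglm"
  out
}

#' @export
print.summary.nbglm <- function(x, ...) {
  cat(sprintf("Negative binomial GLM fits for %d genes\n", x$n_genes))
  cat(sprintf("Converged: %d\n", x$n_converged))
  cat("\nPer-coefficient log2-scale quartiles:\n")
  print(round(x$log2_coef_quartiles, 3))
  cat("\nDispersion:\n")
  print(x$dispersion_summary)
  invisible(x)
}

#' @export
coef.nbglm <- function(object, ...) object$beta / log(2)

#' @export
fitted.nbglm <- function(object, ...) object$fitted

#' @export
logLik.nbglm <- function(object, ...) object$logLik

#' @export
residuals.nbglm <- function(object, type = c("pearson", "deviance"), ...) {
  type <- match.arg(type)
  mu <- object$fitted
  y <- object$counts
  alpha <- object$dispersion
  if (type == "pearson") {
    (y - mu) / sqrt(mu + alpha * mu^2)
  } else {
    size <- 1 / alpha
    ll_sat <- stats::dnbinom(y, size = size, mu = pmax(y, 1e-8), log = TRUE)
    ll_fit <- stats::dnbinom(y, size = size, mu = mu, log = TRUE)
    sign(y - mu) * sqrt(pmax(2 * (ll_sat - ll_fit), 0))
  }
}

# Resolve a contrast specification into a numeric vector over coefficients.
resolve_contrast <- function(fit, contrast) {
  coefs <- colnames(fit$beta)
  if (is.character(contrast)) {
    if (length(contrast) != 1L || !contrast %in% coefs) {
      rc_stop(paste0("unknown coefficient '", paste(contrast, collapse = ","),
                     "'; available: ", paste(coefs, collapse = ", ")),
              "riboclean_contract_error")
    }
    v <- stats::setNames(numeric(length(coefs)), coefs)
    v[contrast] <- 1
    v
  } else if (is.numeric(contrast)) {
    if (!is.null(names(contrast))) {
      unknown <- setdiff(names(contrast), coefs)
      if (length(unknown)) {
        rc_stop(paste0("contrast references unknown coefficient(s): ",
                       paste(unknown, collapse = ", ")),
                "riboclean_contract_error")
      }
      v <- stats::setNames(numeric(length(coefs)), coefs)
      v[names(contrast)] <- contrast
      v
    } else {
      if (length(contrast) != length(coefs)) {
        rc_stop("unnamed contrast must match the number of coefficients",
                "riboclean_contract_error")
      }
      stats::setNames(contrast, coefs)
    }
  } else {
    rc_stop("contrast must be a coefficient name or a numeric vector",
            "riboclean_contract_error")
  }
}

#' Wald test of a linear contrast
#'
#' Tests `c'beta = 0` per gene with the Wald statistic estimate/SE and a
#' two-sided standard-normal p-value; q-values are Benjamini-Hochberg
#' adjusted within the tested gene set. Estimates are reported as log2
#' fold-changes. Genes whose estimate exceeds `lfc_cap` in magnitude
#' (typically because a group mean is zero) are capped there and flagged.
#'
#' @param fit An [nb_glm()] fit.
#' @param contrast Coefficient name, or a (named) numeric contrast vector
#'   over the model coefficients.
#' @param name Label for the contrast (stored in the result).
#' @param lfc_cap Cap (log2 units) for reported fold-changes.
#' @return Data frame of class `de_result`: `gene`, `log2fc`, `se`, `stat`,
#'   `p`, `q`, `mean_norm_count`, `flag`.
#' @export
wald_contrast <- function(fit, contrast, name = NULL, lfc_cap = 10) {
  stopifnot(inherits(fit, "nbglm"))
  v <- resolve_contrast(fit, contrast)
  est <- drop(fit$beta %*% v) / log(2)
  se <- sqrt(pmax(apply(fit$cov, 1, function(S) drop(t(v) %*% S %*% v)),
                  0)) / log(2)
  stat <- ifelse(se > 0, est / se, ifelse(est == 0, 0, sign(est) * Inf))
  p <- 2 * stats::pnorm(-abs(stat))
  p[est == 0] <- 1
  flag <- ifelse(!fit$converged, "no_converge", "")
  capped <- abs(est) > lfc_cap
  est[capped] <- sign(est[capped]) * lfc_cap
  flag[capped] <- paste0(flag[capped], ifelse(nzchar(flag[capped]), ";", ""),
                         "lfc_capped")
  out <- data.frame(
    gene = rownames(fit$beta),
    log2fc = est, se = se, stat = stat, p = p,
    q = stats::p.adjust(p, method = "BH"),
    mean_norm_count = fit$mean_norm_count,
    flag = flag,
    stringsAsFactors = FALSE, row.names = NULL
  )
  attr(out, "contrast") <- if (is.null(name)) {
    paste(deparse(contrast), collapse = "")
  } else {
    name
  }
  class(out) <- c("de_result", "data.frame")
  out
}

#' Likelihood ratio test of a full vs a nested reduced model
#'
#' Refits both designs at the dispersions of the full fit and compares
#' per-gene log-likelihoods: `stat = 2 (ll_full - ll_reduced)`, referred to a
#' chi-square with degrees of freedom equal to the rank difference of the
#' designs. Used for origin-specific effects across all time points at once.
#'
#' @param x A [count_matrix()] (or counts matrix with `meta`).
#' @param full,reduced Model formulas or design matrices; `reduced` must be
#'   nested in `full`.
#' @inheritParams nb_glm
#' @return Data frame of class `de_result` with `stat`, `df`, `p`, `q`; the
#'   reported `log2fc` is the last full-model coefficient not in the reduced
#'   design (for orientation only).
#' @export
lrt_full_vs_reduced <- function(x, full, reduced, meta = NULL,
                                size_factors = NULL, dispersion = "moments") {
  if (inherits(x, "count_matrix") && is.null(meta)) meta <- x$meta
  counts <- if (inherits(x, "count_matrix")) x$counts else as.matrix(x)
  if (is.null(size_factors)) size_factors <- rle_size_factors(counts)
  Xf <- build_design(full, meta)
  Xr <- build_design(reduced, meta)
  # Nesting: the reduced column space must lie inside the full column space.
  if (qr(cbind(Xf, Xr))$rank > qr(Xf)$rank) {
    rc_stop("reduced design is not nested in the full design",
            "riboclean_contract_error")
  }
  df <- qr(Xf)$rank - qr(Xr)$rank
  fit_full <- nb_glm(counts, Xf, meta = meta, size_factors = size_factors,
                     dispersion = dispersion)
  fit_red <- suppressWarnings(
    nb_glm(counts, Xr, meta = meta, size_factors = size_factors,
           dispersion = fit_full$dispersion)
  )
  stat <- pmax(2 * (fit_full$logLik - fit_red$logLik), 0)
  # df = 0 means the designs span the same space: nothing to test, p = 1.
  p <- if (df == 0) rep(1, nrow(counts)) else {
    stats::pchisq(stat, df = df, lower.tail = FALSE)
  }
  extra <- setdiff(colnames(fit_full$beta), colnames(fit_red$beta))
  lfc <- if (length(extra)) {
    fit_full$beta[, extra[length(extra)]] / log(2)
  } else {
    rep(NA_real_, nrow(counts))
  }
  out <- data.frame(
    gene = rownames(counts),
    log2fc = lfc, stat = stat, df = df, p = p,
    q = stats::p.adjust(p, method = "BH"),
    mean_norm_count = fit_full$mean_norm_count,
    flag = ifelse(fit_full$converged & fit_red$converged, "", "no_converge"),
    stringsAsFactors = FALSE, row.names = NULL
  )
  attr(out, "contrast") <- "LRT full vs reduced"
  class(out) <- c("de_result", "data.frame")
  out
}

#' @export
print.de_result <- function(x, ...) {
  cat("Contrast:", attr(x, "contrast"), "\n")
  cat(sprintf("%d genes; %d with q < 0.05\n", nrow(x), sum(x$q < 0.05)))
  print.data.frame(utils::head(x[order(x$p), ], 10), row.names = FALSE)
  invisible(x)
}
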