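test_that("in the large-count, small-dispersion limit the GLM recovers the group-mean ratio", {
  set.seed(2)
  mu1 <- 5000; mu2 <- 20000
  counts <- rbind(g1 = c(rpois(4, mu1), rpois(4, mu2)))
  counts <- rbind(counts, g2 = c(rpois(4, 3000), rpois(4, 3000)))
  colnames(counts) <- paste0("s", 1:8)
  meta <- data.frame(group = rep(c("a", "b"), each = 4))
  fit <- nb_glm(counts, ~ group, meta = meta, size_factors = rep(1, 8),
                dispersion = 1e-8)
  norm_ratio <- mean(counts["g1", 5:8]) / mean(counts["g1", 1:4])
  expect_equal(unname(coef(fit)["g1", "groupb"]), log2(norm_ratio),
               tolerance = 1e-6)
})

test_that("GLM coefficients match a brute-force likelihood grid search on toy genes", {
  set.seed(9)
  group <- rep(c("a", "b"), each = 4)
  sf <- c(0.8, 1.1, 1.0, 0.9, 1.2, 1.0, 0.7, 1.3)
  alpha <- 0.1
  counts <- t(sapply(1:5, function(g) {
    mu <- sf * exp(3 + (g - 3) * 0.6 * (group == "b"))
    rnbinom(8, mu = mu, size = 1 / alpha)
  }))
  dimnames(counts) <- list(paste0("g", 1:5), paste0("s", 1:8))
  fit <- nb_glm(counts, ~ group, meta = data.frame(group = group),
                size_factors = sf, dispersion = alpha)
  for (g in 1:5) {
    oracle <- oracle_grid_fit(counts[g, ], group, sf, alpha)
    expect_equal(unname(fit$beta[g, ]), unname(oracle), tolerance = 1e-3)
  }
})

test_that("a non-full-rank design names its aliased columns", {
  meta <- data.frame(group = rep("a", 4), dup = rep("x", 4))
  counts <- matrix(rpois(8, 20), 2, dimnames = list(c("g1", "g2"),
                                                    paste0("s", 1:4)))
  X <- cbind(intercept = 1, copy = 1)
  expect_error(nb_glm(counts, X, meta = meta, size_factors = rep(1, 4)),
               class = "riboclean_design_error")
  expect_error(nb_glm(counts, X, meta = meta, size_factors = rep(1, 4)),
               "copy")
})

test_that("Wald statistics follow the normal-tail closed form and flag capped estimates", {
  set.seed(3)
  counts <- matrix(rnbinom(6 * 50, mu = 100, size = 10), 50,
                   dimnames = list(sprintf("g%02d", 1:50),
                                   paste0("s", 1:6)))
  counts[1, ] <- c(0L, 0L, 0L, 60L, 55L, 70L)  # zero group mean: capped
  meta <- data.frame(group = rep(c("a", "b"), each = 3))
  fit <- suppressWarnings(nb_glm(counts, ~ group, meta = meta,
                                 size_factors = rep(1, 6),
                                 dispersion = 0.05))
  res <- wald_contrast(fit, "groupb")
  ok <- is.finite(res$stat) & res$flag == ""
  expect_equal(res$p[ok], 2 * pnorm(-abs(res$stat[ok])), tolerance = 1e-12)
  # stat 2 corresponds to p ~ 0.0455 on that closed form
  expect_equal(2 * pnorm(-2), 0.0455, tolerance = 1e-3)
  expect_equal(res$stat[ok], res$log2fc[ok] / res$se[ok], tolerance = 1e-12)
  g1 <- res[res$gene == "g01", ]
  expect_match(g1$flag, "lfc_capped")
  expect_equal(abs(g1$log2fc), 10)

  expect_error(wald_contrast(fit, "nosuchcoef"),
               class = "riboclean_contract_error")
})

test_that("BH adjustment matches the textbook step-up procedure", {
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.9), method = "BH"),
               c(0.04, 0.04, 0.04, 0.9), tolerance = 1e-12)
  for (s in 1:20) {
    set.seed(s)
    p <- runif(1 + s %% 7 * 13)
    expect_equal(p.adjust(p, method = "BH"), oracle_bh(p), tolerance = 1e-12)
  }
  # monotone after sorting by p
  set.seed(99)
  p <- runif(40)
  q <- p.adjust(p, method = "BH")
  expect_true(all(diff(q[order(p)]) >= -1e-12))
})

test_that("the LRT is null at identical designs and reports the rank difference", {
  set.seed(7)
  counts <- matrix(rnbinom(40, mu = 60, size = 8), 5,
                   dimnames = list(paste0("g", 1:5), paste0("s", 1:8)))
  meta <- data.frame(group = rep(c("a", "b"), each = 4))
  same <- lrt_full_vs_reduced(counts, ~ group, ~ group, meta = meta,
                              size_factors = rep(1, 8), dispersion = 0.1)
  expect_true(all(same$stat < 1e-6))
  expect_true(all(same$p == 1))

  out <- lrt_full_vs_reduced(counts, ~ group, ~ 1, meta = meta,
                             size_factors = rep(1, 8), dispersion = 0.1)
  expect_true(all(out$df == 1))
  expect_true(all(out$stat >= 0))

  # non-nested designs are rejected
  meta2 <- data.frame(group = rep(c("a", "b"), each = 4),
                      other = rep(c("x", "y"), 4))
  expect_error(
    lrt_full_vs_reduced(counts, ~ group, ~ other, meta = meta2,
                        size_factors = rep(1, 8), dispersion = 0.1),
    class = "riboclean_contract_error")
})

test_that("the LRT detects a 2-log2-unit interaction with high power", {
  set.seed(15)
  n_rep <- 200
  meta <- data.frame(condition = rep(c("naive", "sci"), each = 6),
                     fraction = rep(rep(c("input", "IP"), each = 3), 2))
  X <- model.matrix(~ condition * fraction, meta)
  beta <- c(5, 0.3, 0.8, 2 * log(2))  # interaction of 2 log2 units
  hits <- 0
  for (r in seq_len(n_rep)) {
    mu <- exp(drop(X %*% beta))
    y <- matrix(rnbinom(12, mu = mu, size = 1 / 0.05), 1,
                dimnames = list("g1", paste0("s", 1:12)))
    res <- lrt_full_vs_reduced(y, ~ condition * fraction,
                               ~ condition + fraction, meta = meta,
                               size_factors = rep(1, 12), dispersion = 0.05)
    if (res$p < 0.05) hits <- hits + 1
  }
  expect_gt(hits / n_rep, 0.9)
})

test_that("Wald and LRT p-values agree in the large-count small-effect regime", {
  set.seed(23)
  meta <- data.frame(group = rep(c("a", "b"), each = 10))
  X <- model.matrix(~ group, meta)
  mu <- exp(drop(X %*% c(8, 0.1)))
  counts <- matrix(rnbinom(20 * 30, mu = rep(mu, each = 30), size = 1 / 0.02),
                   nrow = 30,
                   dimnames = list(sprintf("g%02d", 1:30), paste0("s", 1:20)))
  fit <- nb_glm(counts, ~ group, meta = meta, size_factors = rep(1, 20),
                dispersion = 0.02)
  w <- wald_contrast(fit, "groupb")
  l <- lrt_full_vs_reduced(counts, ~ group, ~ 1, meta = meta,
                           size_factors = rep(1, 20), dispersion = 0.02)
  mid <- w$p > 1e-4   # avoid ratio blow-ups in the extreme tail
  expect_true(all(abs(w$p[mid] - l$p[mid]) / w$p[mid] < 0.2))
})

test_that("model accessors expose coherent per-gene fits", {
  sim <- quick_sim(n_genes = 60, seed = 44)
  cmf <- filter_low_counts(sim$counts)
  fit <- nb_glm(cmf, ~ condition * fraction)
  expect_s3_class(fit, "nbglm")
  expect_equal(dim(coef(fit)), c(nrow(cmf$counts), 8))
  expect_equal(dim(fitted(fit)), dim(cmf$counts))
  r <- residuals(fit, type = "pearson")
  expect_equal(dim(r), dim(cmf$counts))
  expect_lt(abs(mean(r)), 0.5)
  expect_output(print(fit), "nbglm")
  expect_output(print(summary(fit)), "quartiles")
})
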