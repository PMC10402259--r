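test_that("simulation is deterministic given a seed and refuses to run without one", {
  a <- simulate_experiment(sim_config(n_genes = 80, seed = 5))
  b <- simulate_experiment(sim_config(n_genes = 80, seed = 5))
  expect_identical(a$counts$counts, b$counts$counts)
  expect_identical(a$truth, b$truth)
  c <- simulate_experiment(sim_config(n_genes = 80, seed = 6))
  expect_false(identical(a$counts$counts, c$counts$counts))

  expect_error(sim_config(n_genes = 10), class = "riboclean_config_error")
})

test_that("invalid configurations are rejected", {
  bad_prop <- matrix(c(0.7, 0.4, 0.7, 0.6), nrow = 2,
                     dimnames = list(c("naive", "dpi2"),
                                     c("OL", "microglia")))  # naive sums to 1.4
  expect_error(
    sim_config(n_genes = 10, cell_types = c("OL", "microglia"),
               conditions = c("naive", "dpi2"), proportions = bad_prop,
               seed = 1),
    class = "riboclean_config_error")
  expect_error(sim_config(n_genes = 10, contamination_fraction = 1, seed = 1),
               class = "riboclean_config_error")
  expect_error(sim_config(n_genes = 10, dispersion = 0, seed = 1),
               class = "riboclean_config_error")
})

test_that("with one cell type, no contamination and no injury, the expected IP/input ratio is flat across conditions", {
  cfg <- sim_config(
    n_genes = 40, cell_types = "OL",
    conditions = c("naive", "dpi2"),
    proportions = matrix(1, 2, 1, dimnames = list(c("naive", "dpi2"), "OL")),
    contamination_fraction = 0, frac_ol_de = 0, frac_contaminant = 0,
    seed = 2)
  ex <- expected_counts(cfg)
  ratio <- ex$ip / ex$input
  expect_equal(ratio[, "dpi2"], ratio[, "naive"], tolerance = 1e-12)
  expect_equal(unname(ratio[, "naive"]), rep(1, 40), tolerance = 1e-12)
})

test_that("a microglia-only gene follows the ambient surge in IP: closed form matches sample means", {
  # One gene expressed only in microglia; microglial proportion rises 5x at
  # dpi2; 10% contamination. Its expected IP count must rise ~5-fold while
  # its expression in the tagged cell type is 0 throughout.
  n <- 30
  base <- matrix(100, n, 2, dimnames = list(NULL, c("OL", "microglia")))
  base[, "microglia"] <- 0
  base[1, ] <- c(0, 500)  # the contaminant gene
  prop <- matrix(c(0.98, 0.90, 0.02, 0.10), 2, 2,
                 dimnames = list(c("naive", "dpi2"), c("OL", "microglia")))
  L <- 1e5
  cfg <- sim_config(
    n_genes = n, cell_types = c("OL", "microglia"),
    conditions = c("naive", "dpi2"), proportions = prop,
    baseline_expression = base,
    injury_lfc = array(0, dim = c(n, 2, 2)),
    contamination_fraction = 0.1, dispersion = 0.05,
    library_size_range = c(L, L), n_replicates = 500, seed = 8)
  ex <- expected_counts(cfg)

  # Closed form from the mixture definition, computed independently.
  amb <- function(cond) base %*% prop[cond, ] / sum(base %*% prop[cond, ])
  expect_equal(unname(ex$input[, "naive"]), unname(amb("naive")[, 1]),
               tolerance = 1e-12)
  expect_equal(unname(ex$ip[1, "dpi2"] / ex$ip[1, "naive"]),
               unname(amb("dpi2")[1, 1] / amb("naive")[1, 1]),
               tolerance = 1e-12)
  expect_gt(ex$ip[1, "dpi2"] / ex$ip[1, "naive"], 4)
  expect_lt(ex$ip[1, "dpi2"] / ex$ip[1, "naive"], 6)

  # Sample means over >= 1000 NB draws agree with the analytic expectation.
  sim <- simulate_experiment(cfg)
  meta <- sim$counts$meta
  for (cond in c("naive", "dpi2")) {
    ip_cols <- meta$fraction == "IP" & meta$condition == cond
    obs <- mean(sim$counts$counts[1, ip_cols])
    expect_equal(obs, unname(L * ex$ip[1, cond]), tolerance = 0.05)
  }
})

test_that("simulated counts match NB mean and variance at 10,000 draws", {
  L <- 2e5
  cfg <- sim_config(
    n_genes = 50, cell_types = "OL", conditions = "naive",
    proportions = matrix(1, 1, 1, dimnames = list("naive", "OL")),
    contamination_fraction = 0, frac_ol_de = 0, frac_contaminant = 0,
    dispersion = 0.05, library_size_range = c(L, L),
    n_replicates = 5000, seed = 21)
  sim <- simulate_experiment(cfg)
  ex <- expected_counts(cfg)
  ip_cols <- sim$counts$meta$fraction == "IP"   # 5000 IP libraries
  mu <- L * ex$ip[, "naive"]
  big <- mu > 50
  obs_mean <- rowMeans(sim$counts$counts[, ip_cols])
  expect_true(all(abs(obs_mean[big] - mu[big]) / mu[big] < 0.02))
  obs_var <- apply(sim$counts$counts[, ip_cols], 1, var)
  expected_var <- mu + 0.05 * mu^2
  expect_true(all(abs(obs_var[big] - expected_var[big]) /
                    expected_var[big] < 0.10))
})

test_that("a null scenario produces near-nominal downstream DE rates", {
  cfg <- sim_config(n_genes = 200, contamination_fraction = 0,
                    frac_ol_de = 0, frac_contaminant = 0, seed = 31)
  sim <- simulate_experiment(cfg)
  cmf <- filter_low_counts(sim$counts)
  de <- de_condition(cmf, "dpi2")
  expect_lte(mean(de$q < 0.05), 0.07)
})

test_that("truth labels are mutually exclusive and consistent with the parameters", {
  sim <- quick_sim(n_genes = 500, seed = 13)
  expect_false(any(sim$truth$true_de & sim$truth$contaminant_driven))
  # every flagged true responder indeed carries the configured effect size
  expect_true(all(abs(sim$truth$tagged_lfc[sim$truth$true_de]) == 2))
  # contaminant-driven genes never change in the tagged cell type
  expect_true(all(sim$truth$tagged_lfc[sim$truth$contaminant_driven] == 0))
})

test_that("the truth-derived marker panel is specific by construction", {
  sim <- quick_sim(n_genes = 400, seed = 17)
  panel <- marker_panel_from_truth(sim, n_per_type = 10)
  expect_named(panel, sim$config$cell_types)
  idx <- match(panel$OL, rownames(sim$counts$counts))
  expect_true(all(sim$params$primary[idx] == "OL"))
})
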