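fake_de <- function(genes, log2fc, q) {
  data.frame(gene = genes, log2fc = log2fc, q = q, stringsAsFactors = FALSE)
}

test_that("enrichment classification applies effect and significance gates with inclusive ties", {
  tab <- fake_de(paste0("g", 1:7),
                 log2fc = c(2.4, 0.49, 3.0, -0.6, 0.5, 2.0, 0.8),
                 q = c(1e-6, 0.01, 0.2, 0.01, 0.001, 0.001, 0.5))
  out <- classify_enrichment(tab)
  expect_identical(as.character(out$class),
                   c("highly_selective",  # strong and significant
                     "neutral",           # just under the effect threshold
                     "neutral",           # big effect but fails the q gate
                     "depleted",
                     "enriched",          # tie at +0.5 passes
                     "highly_selective",  # tie at +2 passes
                     "neutral"))
  expect_true(all(out$class[out$class == "highly_selective"] >= "enriched"))
})

test_that("two-arm filtration passes arm 1, arm 2, and rejects contamination-like profiles", {
  genes <- c("arm1_gene", "microglia_like", "arm2_gene", "null_gene")
  de <- fake_de(genes,
                log2fc = c(2, 4, 1.2, 0.2),
                q = c(1e-4, 1e-8, 0.01, 0.8))
  delta <- data.frame(gene = genes, condition = "dpi2",
                      delta = c(1.5, 0.05, 0.2, 0),
                      q = c(0.01, 0.9, 0.4, 1))
  enr_naive <- fake_de(genes, log2fc = c(0.2, -2, 1.5, 0),
                       q = c(0.5, 1e-6, 1e-4, 1))
  enr_cond <- fake_de(genes, log2fc = c(0.3, -2.1, 1.6, 0),
                      q = c(0.5, 1e-6, 1e-4, 1))
  rep <- two_arm_filter(de, delta, enr_naive, enr_cond)

  expect_true(rep$final[rep$gene == "arm1_gene"])
  expect_true(rep$arm1[rep$gene == "arm1_gene"])
  # strongly "upregulated" but depleted and with unchanged enrichment:
  # the signature of ambient contamination — rejected
  expect_false(rep$final[rep$gene == "microglia_like"])
  expect_true(rep$de_pass[rep$gene == "microglia_like"])
  # constantly high enrichment rescues a gene with a null delta
  expect_true(rep$final[rep$gene == "arm2_gene"])
  expect_true(rep$arm2[rep$gene == "arm2_gene"])
  expect_false(rep$arm1[rep$gene == "arm2_gene"])
  expect_false(rep$final[rep$gene == "null_gene"])

  s <- attr(rep, "summary")
  expect_equal(unname(s["n_de"]), 3)
  expect_equal(unname(s["n_final"]), 2)
})

test_that("mismatched gene universes are a contract error", {
  genes <- paste0("g", 1:3)
  de <- fake_de(genes, c(2, 2, 2), c(0.01, 0.01, 0.01))
  delta <- data.frame(gene = c("g1", "g2", "OTHER"), condition = "dpi2",
                      delta = c(1.5, 1.5, 1.5), q = rep(0.01, 3))
  enr <- fake_de(genes, rep(1.5, 3), rep(0.01, 3))
  expect_error(two_arm_filter(de, delta, enr, enr),
               class = "riboclean_contract_error")
})

test_that("dropping arm 2 never enlarges the final set; mirrored signs filter downregulation", {
  sim <- quick_sim(n_genes = 300, seed = 8)
  cmf <- filter_low_counts(sim$counts)
  de <- de_condition(cmf, "dpi2")
  delta <- differential_enrichment(cmf, conditions = "dpi2")
  enr_n <- condition_enrichment(cmf, "naive")
  enr_c <- condition_enrichment(cmf, "dpi2")
  rep <- two_arm_filter(de, delta, enr_n, enr_c)
  arm1_only <- rep$de_pass & rep$arm1
  expect_true(all(rep$gene[arm1_only] %in% rep$gene[rep$final]))
  expect_true(sum(arm1_only) <= sum(rep$final))
  # downregulated true responders are recovered with direction "down"
  truth <- sim$truth[sim$truth$condition == "dpi2", ]
  down_true <- truth$gene[truth$true_de & truth$tagged_lfc < 0]
  down_called <- rep$gene[rep$final & rep$direction == "down"]
  expect_gt(length(intersect(down_true, down_called)), 0)
})

test_that("a purely ambient-driven gene shows large IP-fraction DE but a null interaction", {
  # gene 1 lives only in microglia and surges 8-fold there after injury;
  # the tagged (OL) pool never changes, so the interaction must be ~ 0
  # while naive IP-vs-dpi2-IP differential expression is large.
  n <- 60
  base <- matrix(0, n, 2, dimnames = list(NULL, c("OL", "microglia")))
  base[, "OL"] <- 100
  base[1, ] <- c(0, 800)
  lfc <- array(0, dim = c(n, 2, 2))
  lfc[1, 2, 2] <- 3
  true_ol <- 2
  lfc[2, 1, 2] <- true_ol  # gene 2: genuine OL induction
  prop <- matrix(c(0.8, 0.55, 0.2, 0.45), 2, 2,
                 dimnames = list(c("naive", "dpi2"), c("OL", "microglia")))
  cfg <- sim_config(n_genes = n, cell_types = c("OL", "microglia"),
                    conditions = c("naive", "dpi2"), proportions = prop,
                    baseline_expression = base, injury_lfc = lfc,
                    contamination_fraction = 0.1, dispersion = 0.02,
                    n_replicates = 8, library_size_range = c(1e6, 1e6),
                    seed = 77)
  sim <- simulate_experiment(cfg)
  cmf <- filter_low_counts(sim$counts)
  de <- de_condition(cmf, "dpi2")
  delta <- differential_enrichment(cmf, conditions = "dpi2")

  amb_gene <- match("gene0001", delta$gene)
  ol_gene <- match("gene0002", delta$gene)
  # analytic interaction values from the mixture expectations: the raw
  # share double-ratio plus the composition correction that median-of-ratios
  # normalization introduces (identical for every gene)
  ex <- expected_counts(cfg)
  d_share <- log2((ex$ip[, "dpi2"] / ex$ip[, "naive"]) /
                    (ex$input[, "dpi2"] / ex$input[, "naive"]))
  exp_groups <- 1e6 * cbind(ip1 = ex$ip[, "naive"], ip2 = ex$ip[, "dpi2"],
                            in1 = ex$input[, "naive"],
                            in2 = ex$input[, "dpi2"])
  rownames(exp_groups) <- sprintf("gene%04d", seq_len(nrow(exp_groups)))
  sfe <- rle_size_factors(round(exp_groups))
  corr <- log2((sfe["ip1"] * sfe["in2"]) / (sfe["ip2"] * sfe["in1"]))
  d_est <- unname(d_share + corr)

  expect_lt(abs(d_share[1]), 0.05)  # ambient-driven: null by construction
  expect_lt(abs(delta$delta[amb_gene] - d_est[1]),
            4 * delta$se[amb_gene] + 0.05)
  expect_gt(de$log2fc[match("gene0001", de$gene)], 1)
  expect_lt(de$q[match("gene0001", de$gene)], 0.05)

  # genuine OL induction: positive delta recovered within its CI
  expect_gt(d_share[2], 0.5)
  expect_lt(abs(delta$delta[ol_gene] - d_est[2]),
            4 * delta$se[ol_gene] + 0.05)
})

test_that("filtration strictly reduces the contaminant-driven fraction across seeds", {
  worse <- 0
  for (s in 1:20) {
    sim <- quick_sim(n_genes = 300, seed = 100 + s)
    cmf <- filter_low_counts(sim$counts)
    de <- de_condition(cmf, "dpi2")
    delta <- differential_enrichment(cmf, conditions = "dpi2")
    enr_n <- condition_enrichment(cmf, "naive")
    enr_c <- condition_enrichment(cmf, "dpi2")
    rep <- two_arm_filter(de, delta, enr_n, enr_c)
    truth <- sim$truth[sim$truth$condition == "dpi2", ]
    cont <- truth$contaminant_driven[match(rep$gene, truth$gene)]
    frac_unfiltered <- mean(cont[rep$de_pass])
    frac_final <- if (any(rep$final)) mean(cont[rep$final]) else 0
    if (!(frac_final < frac_unfiltered)) worse <- worse + 1
  }
  expect_equal(worse, 0)
})

test_that("the acute-specific rule keeps normalized or halved responders", {
  genes <- c("halved", "sustained", "lost_significance")
  filt <- data.frame(gene = genes, final = TRUE, direction = "up",
                     stringsAsFactors = FALSE)
  de2 <- fake_de(genes, log2fc = c(3.0, 3.0, 2.0), q = c(1e-4, 1e-4, 1e-4))
  de42 <- fake_de(genes, log2fc = c(1.5, 2.9, 1.8), q = c(1e-3, 1e-3, 0.3))
  out <- acute_specific_set(filt, de2, de42)
  expect_setequal(out, c("halved", "lost_significance"))
  expect_false("sustained" %in% out)
})
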