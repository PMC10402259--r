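# Shared fixture builders. All fixtures are constructed in code; nothing is
# read from disk unless a test writes it first.

# A minimal paired IP/input count matrix with explicit counts.
make_cm <- function(counts, conditions = NULL) {
  n_samp <- ncol(counts)
  stopifnot(n_samp %% 2 == 0)
  n_pair <- n_samp / 2
  meta <- data.frame(
    sample = colnames(counts),
    fraction = rep(c("IP", "input"), each = n_pair),
    condition = rep("naive", n_samp),
    pair = rep(paste0("p", seq_len(n_pair)), 2),
    stringsAsFactors = FALSE
  )
  count_matrix(counts, meta, conditions = conditions)
}

# A random valid count matrix for round-trip property tests.
random_cm <- function(n_genes = 20, n_pairs = 3, seed = 1) {
  set.seed(seed)
  counts <- matrix(rnbinom(n_genes * 2 * n_pairs, mu = 50, size = 5),
                   nrow = n_genes,
                   dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                                   sprintf("s%02d", seq_len(2 * n_pairs))))
  make_cm(counts)
}

# Independent median-of-ratios oracle, written as the definition reads.
oracle_rle <- function(counts) {
  n <- nrow(counts)
  geo <- numeric(n)
  for (g in seq_len(n)) geo[g] <- prod(counts[g, ])^(1 / ncol(counts))
  ok <- geo > 0
  sf <- numeric(ncol(counts))
  for (s in seq_len(ncol(counts))) {
    sf[s] <- median(counts[ok, s] / geo[ok])
  }
  sf
}

# Textbook Benjamini-Hochberg step-up, independent of p.adjust.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  # enforce monotonicity from the largest p downwards
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# Exhaustive-counting oracle for the upper-tail hypergeometric probability
# P[K >= k]: number of size-n2 draws from N with at least k of the n1
# marked elements, over all draws.
oracle_hyper_upper <- function(N, n1, n2, k) {
  ks <- max(k, max(0, n2 - (N - n1))):min(n1, n2)
  if (k > min(n1, n2)) return(0)
  sum(choose(n1, ks) * choose(N - n1, n2 - ks)) / choose(N, n2)
}

# Brute-force NB log-likelihood grid search for a one-factor two-group
# design, refined over three passes; the independent oracle for nb_glm.
oracle_grid_fit <- function(y, group, sf, alpha) {
  X <- cbind(1, as.numeric(group == levels(factor(group))[2]))
  loglik <- function(b) {
    mu <- sf * exp(X %*% b)
    sum(dnbinom(y, size = 1 / alpha, mu = mu, log = TRUE))
  }
  centre <- c(log(mean(y / sf) + 0.1), 0)
  width <- c(4, 4)
  for (pass in 1:4) {
    b0s <- seq(centre[1] - width[1], centre[1] + width[1], length.out = 41)
    b1s <- seq(centre[2] - width[2], centre[2] + width[2], length.out = 41)
    grid <- as.matrix(expand.grid(b0s, b1s))
    ll <- apply(grid, 1, loglik)
    centre <- grid[which.max(ll), ]
    width <- width / 10
  }
  centre
}

# A deterministic small simulation for tests that only need structure.
quick_sim <- function(n_genes = 300, seed = 42, ...) {
  simulate_experiment(sim_config(n_genes = n_genes, seed = seed, ...))
}
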