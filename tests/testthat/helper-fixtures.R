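# Shared fixture builders: every fixture is generated in code at test time.

# small multi-type design + counts for marker-model tests
marker_fixture <- function(n_per = 25, K = 4, gene_mean = 30, seed = 7) {
  set.seed(seed)
  labels <- setNames(rep(paste0("c", seq_len(K)), each = n_per),
                     sprintf("cell%03d", seq_len(K * n_per)))
  counts <- matrix(rpois(20 * K * n_per, gene_mean), nrow = 20,
                   dimnames = list(paste0("g", 1:20), names(labels)))
  design <- marker_design(counts, labels)
  list(counts = counts, labels = labels, design = design)
}

# simulate one gene from the printed NB model given extras (beta - 1)
simulate_model_gene <- function(design, extra, rv = 0.8, seed = 1) {
  set.seed(seed)
  mu <- as.numeric(design$x %*% extra) + 0.001
  rnbinom(length(mu), size = mu / rv, prob = 1 / (1 + rv))
}

# rank-based AUROC
auroc <- function(score, truth) {
  r <- rank(score)
  n1 <- sum(truth)
  n0 <- sum(!truth)
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# two-block correlation matrix with noise
two_block_corr <- function(n_half = 10, within = 0.8, noise = 0.05,
                           seed = 1) {
  set.seed(seed)
  n <- 2 * n_half
  C <- matrix(0, n, n)
  C[seq_len(n_half), seq_len(n_half)] <- within
  C[(n_half + 1):n, (n_half + 1):n] <- within
  C <- C + matrix(rnorm(n * n, 0, noise), n, n)
  C <- (C + t(C)) / 2
  diag(C) <- 1
  C
}

# brute-force evaluation of the split objective, written independently of
# split_score: plain double loops over the printed formula
brute_force_split <- function(C, x) {
  n <- nrow(C)
  s <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if ((i <= x && j <= x) || (i > x && j > x)) s <- s + C[i, j]
  }
  s / (x^2 + (n - x)^2)
}
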