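# Shared fixture builders: small, fast configurations used across test files.

tiny_config <- function(seed = 11, ...) {
  sim_config(n_chromosomes = 1L, chrom_length = 150000L, n_genes = 60L,
             gene_length_range = c(900L, 1500L), n_sm_clusters = 1L,
             sm_cluster_size = 5L, seed = seed, ...)
}

small_config <- function(seed = 11, ...) {
  sim_config(n_chromosomes = 2L, chrom_length = 300000L, n_genes = 150L,
             gene_length_range = c(900L, 1800L), n_sm_clusters = 2L,
             sm_cluster_size = 6L, seed = seed, ...)
}

# brute-force windowed mean: the independent oracle for smooth_and_bin
brute_windowed_mean <- function(x, window, step) {
  L <- length(x)
  starts <- seq(0, L - 1, by = step)
  vapply(starts, function(s) {
    e <- min(s + window, L)
    mean(x[(s + 1):e])
  }, numeric(1))
}

# a null NB count matrix with no planted effects
null_counts <- function(n = 2000, reps = 3, mu_log = log(300), size = 20,
                        seed = 1) {
  set.seed(seed)
  base <- exp(rnorm(n, mu_log, 1))
  counts <- sapply(seq_len(2 * reps), function(s) rnbinom(n, mu = base, size = size))
  dimnames(counts) <- list(sprintf("g%d", seq_len(n)),
                           sprintf("s%d", seq_len(2 * reps)))
  count_matrix(counts, groups = rep(c("A", "B"), each = reps))
}

# independent Benjamini-Hochberg step-up, written from the definition
bh_stepup <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# exact upper-tail hypergeometric by direct summation of the pmf written
# from binomial coefficients (independent of stats::phyper)
hyper_tail_bruteforce <- function(k, K, N, n) {
  js <- k:min(K, n)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}
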