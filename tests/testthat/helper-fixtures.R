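# Small fixtures shared across test files; everything is generated in code.

# Compact simulator configuration used where full defaults would be slow.
small_sim <- function(seed = 1, n_cells = 400, ...) {
  sim_config(n_cells = n_cells, n_genes = 80, n_tfs = 9, targets_per_tf = 6,
             seed = seed, ...)
}

# Tiny deterministic count matrix with dimnames.
toy_counts <- function(n_genes = 20, n_cells = 15, seed = 42, lambda = 5) {
  set.seed(seed)
  m <- matrix(rpois(n_genes * n_cells, lambda), n_genes, n_cells,
              dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                              sprintf("c%02d", seq_len(n_cells))))
  m
}

# Normalized matrix of cells lying exactly on a line in gene space, with
# three clusters ordered along the line.
line_matrix <- function(n = 90) {
  pos <- seq(0, 1, length.out = n)
  m <- rbind(gA = 1 + 2 * pos, gB = 3 - pos, gC = 0.5 + 0.5 * pos,
             gD = 2 * pos, gE = rep(1, n))
  colnames(m) <- sprintf("cell%03d", seq_len(n))
  clusters <- rep(c("MG", "progenitor", "neuron"), each = n / 3)
  list(m = m, clusters = setNames(clusters, colnames(m)), pos = pos)
}

# Independent hypergeometric upper-tail probability by direct enumeration
# over the count distribution (choose() sums; no phyper).
hyper_upper_enum <- function(N, K, n, k) {
  js <- k:min(K, n)
  js <- js[js >= max(0, n - (N - K))]
  if (length(js) == 0) return(0)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}
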