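# Independent oracles used across the suite.

# Hadamard matrix from the Kronecker recursion H^{2^d} = H^2 (x) H^{2^(d-1)}
kron_hadamard <- function(d) {
  H <- matrix(1)
  H2 <- matrix(c(1, 1, 1, -1), 2, 2)
  for (i in seq_len(d)) H <- kronecker(H2, H)
  H
}

# brute-force enumeration of all +/-1 vectors via expand.grid, reordered to
# the canonical convention (bit i-1 of index <-> coordinate i, bit 0 -> +1)
brute_enumeration <- function(d) {
  g <- as.matrix(expand.grid(rep(list(c(1, -1)), d)))
  idx <- as.integer((1 - g) %*% (2^(0:(d - 1))) / 2)
  unname(g[order(idx), , drop = FALSE])
}

# the five-site worked-example function: 12 x1 x4 - 3 x3 + 6 x1 x2 x5
worked_example_pbf <- function() {
  pbf(c(mask_from_sites(c(1, 4), 5),
        mask_from_sites(3, 5),
        mask_from_sites(c(1, 2, 5), 5)),
      c(12, -3, 6), 5)
}

# random sparse pbf with integer-ish coefficients away from zero
random_sparse_pbf <- function(d, k, seed) {
  set.seed(seed)
  masks <- character(0)
  while (length(masks) < k) {
    o <- sample.int(min(d, 5), 1)
    masks <- unique(c(masks, mask_from_sites(sample.int(d, o), d)))
  }
  pbf(masks[seq_len(k)],
      sample(c(-1, 1), k, TRUE) * stats::runif(k, 1, 10), d)
}

# tiny paired dataset for training tests
toy_training_data <- function(d, n, truth, sigma, seed) {
  X <- sample_dataset(d, n, seed = seed)
  set.seed(seed + 500)
  y <- eval_pbf(truth, X) + stats::rnorm(n, 0, sigma)
  list(X = X, y = y)
}
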