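# Shared fixture builders and independent oracles.

# Brute-force hypergeometric tail by enumerating all C(N, n) draws from a
# labelled universe; independent of ora_pvalue's phyper route.
enumerate_ora_pvalue <- function(k, K, n, N) {
  universe <- c(rep(TRUE, K), rep(FALSE, N - K))
  draws <- utils::combn(N, n)
  hits <- colSums(matrix(universe[draws], nrow = n))
  mean(hits >= k)
}

# Small two-class, clearly separable dataset: one informative feature.
separable_2class <- function(n_per = 6, p = 4, gap = 10, seed = 42) {
  set.seed(seed)
  X <- matrix(rnorm(2 * n_per * p), 2 * n_per, p)
  y <- rep(c("A", "B"), each = n_per)
  X[, 1] <- X[, 1] + ifelse(y == "A", 0, gap)
  list(X = X, y = y)
}

# Four-class dataset on the log scale with strong class structure, built
# directly (not via the generator) so classifier tests have an independent
# construction.
separable_4class <- function(n_per = 10, p = 30, gap = 4, noise = 0.5,
                             seed = 99) {
  set.seed(seed)
  classes <- c("CTRL", "M", "H2O2", "M+H2O2")
  y <- rep(classes, each = n_per)
  X <- matrix(rnorm(4 * n_per * p, sd = noise), 4 * n_per, p)
  for (k in seq_along(classes)) {
    rows <- y == classes[k]
    X[rows, k] <- X[rows, k] + gap   # class k marked by feature k
  }
  colnames(X) <- paste0("F", seq_len(p))
  list(X = X, y = y)
}
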