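# toy with both group means on the (1,1)/(-1,-1) diagonal; already centered
toy4 <- function() {
  expression_dataset(matrix(c(2, 0, 0, 2, -2, 0, 0, -2), 4, 2, byrow = TRUE),
                     c("A", "A", "B", "B"))
}

# two well-separated spherical clusters; linearly separable with margin
separable_dataset <- function(n_per = 10, p = 6, gap = 8, sd = 0.3) {
  x <- matrix(rnorm(2 * n_per * p, sd = sd), 2 * n_per, p)
  x[seq_len(n_per), seq_len(3)] <- x[seq_len(n_per), seq_len(3)] + gap
  expression_dataset(x, rep(c("g1", "g2"), each = n_per))
}

# pure noise, no class signal
noise_dataset <- function(n_per = 10, p = 20, sd = 1) {
  expression_dataset(matrix(rnorm(2 * n_per * p, sd = sd), 2 * n_per, p),
                     rep(c("g1", "g2"), each = n_per))
}

# random two-group data with a mild mean shift on the first `k` features
rand_dataset <- function(n_per = 10, p = 20, shift = 1, k = 3) {
  x <- matrix(rnorm(2 * n_per * p), 2 * n_per, p)
  x[seq_len(n_per), seq_len(k)] <- x[seq_len(n_per), seq_len(k)] + shift
  expression_dataset(x, rep(c("g1", "g2"), each = n_per))
}

# brute-force prior-weighted between-group matrix B = sum_g pi_g m_g m_g'
brute_force_B <- function(xc, labels, priors) {
  lv <- sort(unique(as.character(labels)))
  B <- matrix(0, ncol(xc), ncol(xc))
  for (j in seq_along(lv)) {
    m <- colMeans(xc[labels == lv[j], , drop = FALSE])
    B <- B + priors[j] * m %o% m
  }
  B
}
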