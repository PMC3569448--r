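test_that("candidate weights obey the gamma endpoint semantics", {
  # feature 1: high sd, moderate correlation; feature 2: perfectly correlated
  c0 <- c(1, 1, -1, -1)
  x <- cbind(c(3, -1, 1, -3), c0)       # sd ratio 2.2:1, |rho| 0.45 vs 1
  d <- expression_dataset(x, c("A", "A", "B", "B"))
  ctr <- center_columns(d$x)
  dm <- dummy_code(d$labels)
  wts <- sample_weights(d$labels)

  w0 <- candidate_weights(ctr$x, dm, wts, 0)$matrix
  expect_equal(abs(w0[, 1]), c(1, 0))          # max-sd indicator
  w1 <- candidate_weights(ctr$x, dm, wts, 1)$matrix
  expect_equal(abs(w1[, 1]), c(0, 1))          # max-|rho| indicator
  expect_error(candidate_weights(ctr$x, dm, wts, 1.2), "\\[0, 1\\]")

  # gamma = 0.5: both exponents are 1, columns collinear with covariance weights
  set.seed(21)
  dr <- rand_dataset(n_per = 9, p = 18)
  xc <- center_columns(dr$x)$x
  dmr <- dummy_code(dr$labels)
  wtr <- sample_weights(dr$labels)
  W <- candidate_weights(xc, dmr, wtr, 0.5)$matrix
  for (j in 1:2) {
    cv <- drop(crossprod(xc, scale(dmr$D[, j], scale = FALSE))) / nrow(xc)
    expect_gt(abs(sum(W[, j] * cv / sqrt(sum(cv^2)))), 1 - 1e-10)
  }
  expect_equal(colSums(W^2), rep(1, 2), tolerance = 1e-10)
})

test_that("zero-variance features receive weight zero at every gamma", {
  x <- cbind(matrix(rnorm(20), 10, 2), rep(3.7, 10))
  d <- expression_dataset(x, rep(c("A", "B"), each = 5))
  ctr <- center_columns(d$x)
  dm <- dummy_code(d$labels)
  wts <- sample_weights(d$labels)
  for (g in c(0, 0.2, 0.5, 0.8, 1)) {
    W <- candidate_weights(ctr$x, dm, wts, g)$matrix
    expect_equal(W[3, ], c(0, 0))
  }
})

test_that("cca objective matches the degenerate cases and a grid-search oracle", {
  # one feature equal to the signed class vector -> canonical correlation 1
  set.seed(31)
  c0 <- rep(c(1, -1), each = 6)
  x <- cbind(c0, matrix(rnorm(12 * 4, sd = 0.2), 12, 4))
  d <- expression_dataset(x, rep(c("A", "B"), each = 6))
  ob <- cca_objective(center_columns(d$x)$x, dummy_code(d$labels),
                      sample_weights(d$labels), 1)
  expect_equal(ob$value, 1, tolerance = 1e-6)

  # projection orthogonal to the class vector -> objective ~ 0
  xo <- matrix(rnorm(12 * 5), 12, 5)
  xo <- qr.resid(qr(cbind(1, c0)), xo)      # remove class signal exactly
  do <- expression_dataset(xo, rep(c("A", "B"), each = 6))
  obo <- cca_objective(center_columns(do$x)$x, dummy_code(do$labels),
                       sample_weights(do$labels), 0.5)
  expect_lt(obo$value, 1e-6)

  # random instance vs brute-force maximisation over the Z-combination angle
  set.seed(32)
  dr <- rand_dataset(n_per = 10, p = 10, shift = 0.8)
  xc <- center_columns(dr$x)$x
  dm <- dummy_code(dr$labels)
  wts <- sample_weights(dr$labels)
  for (gamma in c(0.3, 0.6)) {
    W <- candidate_weights(xc, dm, wts, gamma)$matrix
    Z <- xc %*% W
    cs <- dm$signed - mean(dm$signed)
    best <- 0
    for (th in seq(0, pi, by = pi / 4000)) {
      z <- Z %*% c(cos(th), sin(th))
      if (stats::sd(z) > 0) best <- max(best, abs(stats::cor(z, cs)))
    }
    ob <- cca_objective(xc, dm, wts, gamma)
    expect_equal(ob$value, best, tolerance = 1e-3)
    # invariant to positive rescaling of the candidate columns
    expect_true(ob$value >= 0 && ob$value <= 1)
  }
})

test_that("gamma_cc optimisation matches an exhaustive fine grid", {
  # a feature equal to the class vector among equal-sd noise: endpoint 1 wins
  set.seed(41)
  c0 <- rep(c(1, -1), each = 8)
  noise <- matrix(rnorm(16 * 9), 16, 9)
  noise <- qr.resid(qr(cbind(1, c0)), noise)
  noise <- sweep(noise, 2, apply(noise, 2, sd), "/") * 2  # equal sd, larger
  x <- cbind(c0, noise)                   # max-|rho| and max-sd features differ
  d <- expression_dataset(x, rep(c("A", "B"), each = 8))
  res <- optimize_gamma_cc(center_columns(d$x)$x, dummy_code(d$labels),
                           sample_weights(d$labels))
  expect_equal(res$gamma_cc, 1)
  expect_equal(res$objective, 1, tolerance = 1e-6)

  # random instances: optimizer within 0.01 of a 0.001-step grid search
  set.seed(42)
  for (i in 1:3) {
    dr <- rand_dataset(n_per = 12, p = 40, shift = 0.6, k = 4)
    xc <- center_columns(dr$x)$x
    dm <- dummy_code(dr$labels)
    wts <- sample_weights(dr$labels)
    f <- function(g) cca_objective(xc, dm, wts, g)$value
    grid <- seq(0, 1, by = 0.001)
    vals <- vapply(grid, f, 0)
    res <- optimize_gamma_cc(xc, dm, wts)
    expect_lt(abs(res$objective - max(vals)), 1e-4)
    expect_lt(abs(res$gamma_cc - grid[which.max(vals)]), 0.01)
  }
})

test_that("fixed gamma = 0.5 reproduces PLS-DA scores for two balanced groups", {
  set.seed(51)
  d <- rand_dataset(n_per = 15, p = 60, shift = 0.7, k = 5)
  m_pls <- fit_plsda(d, n_components = 4)
  m_pp <- fit_pplsda(d, n_components = 4, gamma = 0.5)
  expect_lt(max(abs(m_pls$training_scores - m_pp$training_scores)), 1e-8)
  expect_lt(max(abs(m_pls$weights - m_pp$weights)), 1e-8)
})

test_that("per-component cc fitting concentrates on a dominant feature", {
  set.seed(61)
  c0 <- rep(c(1, -1), each = 10)
  x <- cbind(c0 + rnorm(20, sd = 0.05), matrix(rnorm(20 * 30, sd = 1), 20, 30))
  d <- expression_dataset(x, rep(c("A", "B"), each = 10))
  m <- fit_pplsda(d, n_components = 1, gamma = "cc")
  expect_gt(abs(m$weights[1, 1]), 0.99)

  m3 <- fit_pplsda(d, n_components = 3, gamma = "cc")
  expect_length(m3$gamma_per_component, 3)
  S <- m3$training_scores
  cs <- crossprod(S) / outer(sqrt(colSums(S^2)), sqrt(colSums(S^2)))
  expect_lt(max(abs(cs[upper.tri(cs)])), 1e-8)
})

test_that("near-endpoint gamma converges to the indicator rule", {
  set.seed(71)
  dr <- rand_dataset(n_per = 10, p = 15, shift = 2, k = 1)
  xc <- center_columns(dr$x)$x
  dm <- dummy_code(dr$labels)
  wts <- sample_weights(dr$labels)
  W1 <- candidate_weights(xc, dm, wts, 1)$matrix
  W99 <- candidate_weights(xc, dm, wts, 0.999)$matrix
  i <- which(abs(W1[, 1]) == 1)
  expect_gt(abs(W99[i, 1]), 0.99)
})

test_that("objective is invariant to feature order and label swap", {
  set.seed(81)
  d <- rand_dataset(n_per = 8, p = 12)
  xc <- center_columns(d$x)$x
  dm <- dummy_code(d$labels)
  wts <- sample_weights(d$labels)
  v1 <- cca_objective(xc, dm, wts, 0.7)$value

  perm <- sample(ncol(xc))
  v2 <- cca_objective(xc[, perm], dm, wts, 0.7)$value
  expect_equal(v1, v2, tolerance = 1e-12)

  lab2 <- ifelse(as.character(d$labels) == "g1", "g2", "g1")
  v3 <- cca_objective(xc, dummy_code(lab2), sample_weights(lab2), 0.7)$value
  expect_equal(v1, v3, tolerance = 1e-12)
})

test_that("loading weights concentrate on the DEGs increasingly with gamma", {
  set.seed(91)
  gammas <- c(0.5, 0.6, 0.7, 0.8, 0.9)
  ratios <- matrix(0, 6, length(gammas))
  for (r in 1:6) {
    d <- simulate_case(simulation_design(case = 3))
    tr <- subset_samples(d, outer_split(d)$train)
    for (j in seq_along(gammas)) {
      m <- fit_pplsda(tr, n_components = 1, gamma = gammas[j])
      w <- abs(m$weights[, 1])
      ratios[r, j] <- mean(w[1:10]) / mean(w[-(1:10)])
    }
  }
  avg <- colMeans(ratios)
  expect_true(all(avg > 1))                  # DEGs outweigh null features
  expect_true(all(diff(avg) > 0))            # and increasingly so with gamma
})
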