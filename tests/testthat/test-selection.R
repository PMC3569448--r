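test_that("gamma grids are equidistant with both endpoints", {
  g <- gamma_grid(0.1)
  expect_length(g$values, 11)
  expect_equal(g$values[c(1, 11)], c(0, 1))
  expect_equal(diff(g$values), rep(0.1, 10))
  expect_length(gamma_grid(0.05)$values, 21)
  expect_error(gamma_grid(0.3), "does not divide")
  expect_error(gamma_grid(0), "\\(0, 0.5\\]")
})

test_that("Monte-Carlo splits are stratified, disjoint and reproducible", {
  lab <- rep(c("a", "b"), each = 10)
  set.seed(1)
  sp <- mc_split(lab)
  expect_equal(as.vector(table(lab[sp$train])), c(7L, 7L))
  expect_equal(as.vector(table(lab[sp$test])), c(3L, 3L))
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), 1:20)

  lab84 <- rep(c("a", "b"), each = 42)
  set.seed(2)
  sp84 <- mc_split(lab84)
  expect_equal(as.vector(table(lab84[sp84$train])), c(29L, 29L))  # round(29.4)
  expect_length(sp84$test, 26)

  set.seed(9); s1 <- mc_split(lab)
  set.seed(9); s2 <- mc_split(lab)
  expect_identical(s1, s2)
  expect_error(mc_split(rep(c("a", "b"), c(1, 19))), "too small")
})

test_that("the half-away-from-zero rounding drives the split sizes", {
  lab25 <- rep(c("a", "b"), c(25, 25))
  set.seed(3)
  sp <- mc_split(lab25)
  expect_equal(length(sp$train), 36)        # round(17.5) = 18 per group
})

test_that("joint selection honours the tie-break and the aggregation order", {
  set.seed(11)
  d <- separable_dataset(n_per = 10)
  sel <- select_gamma_pe(d, grid = gamma_grid(0.5), q = 4, max_components = 3)
  expect_equal(sel$achieved_mean_pe, 0)
  expect_equal(sel$ncomp_star, 1L)          # ties -> fewest components
  expect_equal(sel$gamma_star, 0)           # then smallest gamma

  # aggregation recomputed by hand from the returned tensor
  set.seed(12)
  d2 <- rand_dataset(n_per = 8, p = 10, shift = 1.2)
  sel2 <- select_gamma_pe(d2, grid = gamma_grid(0.5), q = 2, max_components = 2)
  pe <- sel2$pe_tensor
  expect_true(all(pe >= 0 & pe <= 1))
  manual_mean <- (pe[, 1, ] + pe[, 2, ]) / 2
  expect_equal(unname(sel2$mean_pe), unname(manual_mean))
  per_gamma_a <- unname(apply(unname(manual_mean), 1, which.min))
  per_gamma <- manual_mean[cbind(1:3, per_gamma_a)]
  gi <- which(per_gamma <= min(per_gamma) + 1e-12)[1]
  expect_equal(sel2$gamma_star, c(0, 0.5, 1)[gi])
  expect_equal(sel2$ncomp_star, as.integer(per_gamma_a[gi]))
})

test_that("correlation-dominated signal pushes the selected gamma above 0.5", {
  set.seed(13)
  n_per <- 21
  c0 <- rep(c(1, -1), each = n_per)
  x <- matrix(rnorm(2 * n_per * 60), 2 * n_per, 60)
  x <- sweep(x, 2, apply(x, 2, sd), "/")          # uninformative, equal sd
  x[, 1] <- 0.25 * x[, 1] + c0                    # one high-correlation feature
  d <- expression_dataset(x, rep(c("A", "B"), each = n_per))
  sel <- select_gamma_pe(d, q = 10)
  expect_gte(sel$gamma_star, 0.5)
})

test_that("selection is reproducible and identical across engines", {
  set.seed(14)
  d <- rand_dataset(n_per = 12, p = 40, shift = 0.8)
  set.seed(7)
  a <- select_gamma_pe(d, grid = gamma_grid(0.5), q = 3, max_components = 3,
                       engine = "cpp")
  set.seed(7)
  b <- select_gamma_pe(d, grid = gamma_grid(0.5), q = 3, max_components = 3,
                       engine = "r")
  expect_identical(a$pe_tensor, b$pe_tensor)
  expect_identical(a$gamma_star, b$gamma_star)
  set.seed(7)
  a2 <- select_gamma_pe(d, grid = gamma_grid(0.5), q = 3, max_components = 3)
  expect_identical(a$pe_tensor, a2$pe_tensor)

  # the partition (no-resampling) variant is deterministic too
  set.seed(8)
  p1 <- select_gamma_pe(d, grid = gamma_grid(0.5), q = 3, max_components = 3,
                        resample = "partition")
  set.seed(8)
  p2 <- select_gamma_pe(d, grid = gamma_grid(0.5), q = 3, max_components = 3,
                        resample = "partition", engine = "r")
  expect_identical(p1$pe_tensor, p2$pe_tensor)
})

test_that("truncating a five-component fit equals refitting at each count", {
  set.seed(15)
  d <- rand_dataset(n_per = 12, p = 50, shift = 0.6)
  te <- rand_dataset(n_per = 6, p = 50, shift = 0.6)
  for (g in c(0.3, 0.8)) {
    m5 <- fit_pplsda(d, n_components = 5, gamma = g)
    for (a in 1:4) {
      ma <- fit_pplsda(d, n_components = a, gamma = g)
      expect_lt(max(abs(m5$training_scores[, 1:a] - ma$training_scores)), 1e-10)
      expect_lt(max(abs(project(m5, te$x)[, 1:a] - project(ma, te$x))), 1e-10)
    }
  }
})

test_that("component-count cross-validation prefers rank-1 signal and is exact", {
  set.seed(16)
  d <- separable_dataset(n_per = 12, gap = 10)
  nc <- select_ncomp_cv(d, "plsda")
  expect_equal(as.integer(nc), 1L)
  expect_length(attr(nc, "mean_pe"), 5)
  expect_true(all(attr(nc, "mean_pe") >= 0 & attr(nc, "mean_pe") <= 1))

  set.seed(17)
  dn <- noise_dataset(n_per = 10, p = 15)
  ncn <- select_ncomp_cv(dn, "pplsda_fixed", gamma = 0.5)
  expect_true(as.integer(ncn) %in% 1:5)

  set.seed(18); n1 <- select_ncomp_cv(d, "plsda")
  set.seed(18); n2 <- select_ncomp_cv(d, "plsda")
  expect_identical(attr(n1, "mean_pe"), attr(n2, "mean_pe"))

  # the cc variant goes through the reference fitting path
  set.seed(19)
  dcc <- rand_dataset(n_per = 10, p = 20, shift = 1.5)
  nc_cc <- select_ncomp_cv(dcc, "pplsda_cc", repeats = 4)
  expect_true(as.integer(nc_cc) %in% 1:5)
})

test_that("PLS-DA and fixed gamma = 0.5 share one inner-CV kernel legitimately", {
  set.seed(20)
  d <- rand_dataset(n_per = 12, p = 30, shift = 0.8)
  set.seed(5)
  na <- select_ncomp_cv(d, "plsda")
  set.seed(5)
  nb <- select_ncomp_cv(d, "pplsda_fixed", gamma = 0.5)
  expect_identical(attr(na, "mean_pe"), attr(nb, "mean_pe"))
})
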