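test_that("delimited tables round-trip through load_dataset, either orientation", {
  d <- expression_dataset(matrix(c(1.5, 2, 3, 4, 5, 6, 7, 8, 9.25, 10, 11, 12),
                                 4, 3),
                          c("A", "A", "B", "B"),
                          sample_ids = paste0("s", 1:4),
                          feature_ids = paste0("f", 1:3))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_dataset(d, f)
  d2 <- load_dataset(f, label_source = "class")
  expect_equal(d2$x, d$x)
  expect_equal(as.character(d2$labels), as.character(d$labels))
  expect_equal(dim(d2), c(4L, 3L))

  # transposed file (features in rows) + companion label file
  ft <- withr::local_tempfile(fileext = ".csv")
  tab <- data.frame(feature = d$feature_ids, t(d$x), check.names = FALSE)
  write.table(tab, ft, sep = ",", quote = FALSE, row.names = FALSE)
  fl <- withr::local_tempfile(fileext = ".csv")
  write.table(data.frame(id = d$sample_ids, class = as.character(d$labels)),
              fl, sep = ",", quote = FALSE, row.names = FALSE)
  d3 <- load_dataset(ft, label_source = fl, samples_in_rows = FALSE)
  expect_equal(unname(d3$x), unname(d$x))
  expect_equal(as.character(d3$labels), as.character(d$labels))
})

test_that("load_dataset names the offending cell and rejects bad label sets", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tclass\tf1\tf2",
               "s1\tA\t1\t2", "s2\tA\t3\tNA",
               "s3\tB\t5\t6", "s4\tB\t7\t8"), f)
  expect_error(load_dataset(f, "class"), "row 2, column 'f2'")

  writeLines(c("id\tclass\tf1\tf2",
               "s1\tA\t1\t2", "s2\tA\tx\t4",
               "s3\tB\t5\t6", "s4\tB\t7\t8"), f)
  expect_error(load_dataset(f, "class"), "non-numeric cell in row 2")

  writeLines(c("id\tclass\tf1\tf2",
               "s1\tA\t1\t2", "s2\tB\t3\t4",
               "s3\tC\t5\t6", "s4\tC\t7\t8"), f)
  expect_error(load_dataset(f, "class"), "exactly 2 levels")

  writeLines(c("id\tclass\tf1\tf2",
               "s1\tA\t1\t2", "s1\tA\t3\t4",
               "s3\tB\t5\t6", "s4\tB\t7\t8"), f)
  expect_error(load_dataset(f, "class"), "duplicate sample id")
})

test_that("dummy coding follows sorted group order with +1 for the first group", {
  dc <- dummy_code(c("A", "A", "B"))
  expect_equal(unname(dc$D), matrix(c(1, 1, 0, 0, 0, 1), 3, 2))
  expect_equal(dc$signed, c(1, 1, -1))
  expect_equal(dummy_code(c("B", "A", "B"))$D,
               matrix(c(0, 1, 0, 1, 0, 1), 3, 2,
                      dimnames = list(NULL, c("A", "B"))))
  expect_error(dummy_code(c("A", "A", "A")), "exactly 2")
  # row sums 1, column sums = group sizes
  set.seed(1)
  for (i in 1:20) {
    lab <- sample(c("x", "y"), 12, replace = TRUE)
    if (length(unique(lab)) < 2) next
    dc <- dummy_code(lab)
    expect_equal(rowSums(dc$D), rep(1, 12))
    expect_equal(unname(colSums(dc$D)), as.vector(table(lab)[dc$levels]))
  }
})

test_that("relabelling permutes the dummy columns consistently", {
  set.seed(42)
  for (i in 1:10) {
    lab <- sample(c("a", "b"), 10, replace = TRUE)
    if (length(unique(lab)) < 2) next
    dc <- dummy_code(lab)
    # swap the symbols: "a" <-> "z" reverses the sorted order
    lab2 <- ifelse(lab == "a", "z", "b")
    dc2 <- dummy_code(lab2)
    expect_equal(unname(dc2$D), unname(dc$D[, c(2, 1)]))
    expect_equal(dc2$signed, -dc$signed)
  }
})

test_that("centering is exact, reversible, and applies to held-out rows", {
  cc <- center_columns(matrix(c(1, 3), 2, 1))
  expect_equal(cc$x, matrix(c(-1, 1), 2, 1))
  expect_equal(unname(cc$means), 2)
  expect_equal(apply_centering(matrix(5, 1, 1), cc$means), matrix(3, 1, 1))

  m <- matrix(rnorm(50), 10, 5)
  ctr <- center_columns(m)
  expect_lt(max(abs(colMeans(ctr$x))), 1e-10)
  # already-centered input is unchanged
  again <- center_columns(ctr$x)
  expect_equal(again$x, ctr$x, tolerance = 1e-12)
  expect_lt(max(abs(again$means)), 1e-12)
  # reconstruction
  expect_equal(sweep(ctr$x, 2, ctr$means, "+"), m, ignore_attr = TRUE)
})

test_that("sample weights follow the prior/(group size * n) rule", {
  w <- sample_weights(c("A", "A", "B", "B"), priors = c(0.5, 0.5))
  expect_equal(unname(w$weight_diagonal), rep(0.0625, 4))

  w2 <- sample_weights(c("A", "A", "A", "B"), priors = c(0.5, 0.5))
  expect_equal(unname(w2$weight_diagonal), c(rep(0.5 / 12, 3), 0.5 / 4))

  w3 <- sample_weights(rep(c("A", "B"), each = 5), priors = c(0.9, 0.1))
  expect_equal(unname(w3$weight_diagonal[1] / w3$weight_diagonal[10]), 9)

  expect_error(sample_weights(c("A", "B", "A", "B"), priors = c(-0.1, 1.1)),
               "nonnegative")
  # empirical priors give the constant 1/n^2 for any group sizes
  w4 <- sample_weights(c("A", "A", "A", "B", "B"))
  expect_equal(unname(w4$weight_diagonal), rep(1 / 25, 5))
})

test_that("equal priors on balanced data are a no-op for the fits", {
  set.seed(7)
  d <- rand_dataset(n_per = 8, p = 15)
  m1 <- fit_pplsda(d, priors = "empirical", n_components = 2, gamma = 0.7)
  m2 <- fit_pplsda(d, priors = c(0.5, 0.5), n_components = 2, gamma = 0.7)
  expect_lt(max(abs(m1$training_scores - m2$training_scores)), 1e-8)
  p1 <- fit_plsda(d, priors = "empirical", n_components = 2)
  p2 <- fit_plsda(d, priors = c(0.5, 0.5), n_components = 2)
  expect_lt(max(abs(p1$training_scores - p2$training_scores)), 1e-8)
})
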