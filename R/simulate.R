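#' Design of a simulated two-class expression dataset
#'
#' The benchmark family: normally distributed log-scale expression for two
#' classes of 60 samples each over 1000 independent genes, of which 10 are
#' differentially expressed with a per-gene mean class difference delta. Every
#' gene carries the biological variance sigma_b^2 = 0.04 plus a case-dependent
#' technical variance sigma_t^2. The five canonical cases:
#'
#' | case | sigma_t^2        | delta            |
#' |------|------------------|------------------|
#' | 1    | 0                | U\[0.1, 0.5\]    |
#' | 2    | sigma_b^2 / 4    | U\[0.1, 0.5\]    |
#' | 3    | sigma_b^2        | U\[0.1, 0.5\]    |
#' | 4    | sigma_b^2        | 0.2 (fixed)      |
#' | 5    | sigma_b^2        | 0.5 (fixed)      |
#'
#' @param case integer 1 to 5 selecting a canonical case, or `NULL` to set
#'   `sigma_t2` and `delta` directly.
#' @param n_per_class samples per class (60).
#' @param p number of genes (1000).
#' @param n_deg number of differentially expressed genes (10).
#' @param sigma_b2 biological variance (0.04).
#' @param sigma_t2 technical variance; required when `case` is `NULL`.
#' @param delta either a length-2 range for a uniform draw or a single fixed
#'   mean class difference; required when `case` is `NULL`.
#' @param baseline_mean mean of the non-informative genes (0; immaterial
#'   downstream because every fit centers columns, but exposed regardless).
#' @return A `simulation_design`.
#' @export
simulation_design <- function(case = NULL, n_per_class = 60L, p = 1000L,
                              n_deg = 10L, sigma_b2 = 0.04, sigma_t2 = NULL,
                              delta = NULL, baseline_mean = 0) {
  if (!is.null(case)) {
    case <- as.integer(case)
    if (is.na(case) || case < 1L || case > 5L)
      .stopf("case must be an integer between 1 and 5")
    sigma_t2 <- c(0, sigma_b2 / 4, sigma_b2, sigma_b2, sigma_b2)[case]
    delta <- switch(case, c(0.1, 0.5), c(0.1, 0.5), c(0.1, 0.5), 0.2, 0.5)
  }
  if (is.null(sigma_t2) || is.null(delta))
    .stopf("either give a case id or both sigma_t2 and delta")
  if (sigma_b2 < 0 || sigma_t2 < 0) .stopf("variances must be nonnegative")
  if (sigma_b2 + sigma_t2 <= 0) .stopf("total variance must be positive")
  if (n_deg > p) .stopf("n_deg (%d) exceeds p (%d)", n_deg, p)
  if (n_per_class < 2L) .stopf("need at least 2 samples per class")
  if (!length(delta) %in% 1:2 || any(delta < 0))
    .stopf("delta must be a nonnegative value or range")
  structure(list(case = case, n_per_class = as.integer(n_per_class),
                 p = as.integer(p), n_deg = as.integer(n_deg),
                 sigma_b2 = sigma_b2, sigma_t2 = sigma_t2,
                 delta = delta, baseline_mean = baseline_mean),
            class = "simulation_design")
}

#' @export
print.simulation_design <- function(x, ...) {
  dl <- if (length(x$delta) == 2L)
    sprintf("U[%g, %g]", x$delta[1L], x$delta[2L]) else sprintf("%g", x$delta)
  cat(sprintf(paste0("simulation_design%s: %d + %d samples, %d genes ",
                     "(%d DEG, delta ~ %s), sigma_b2 = %g, sigma_t2 = %g\n"),
              if (is.null(x$case)) "" else sprintf(" (case %d)", x$case),
              x$n_per_class, x$n_per_class, x$p, x$n_deg, dl,
              x$sigma_b2, x$sigma_t2))
  invisible(x)
}

#' Simulate one dataset from a design
#'
#' Non-informative genes are iid Normal(baseline_mean, sigma_b^2 + sigma_t^2)
#' in both classes; the first `n_deg` genes additionally receive a +delta_j
#' mean shift in the first class, with delta_j drawn once per dataset
#' (uniformly from the design range, or fixed). Genes are independent. Uses
#' the caller's RNG stream.
#'
#' @param design a [simulation_design()].
#' @return An [expression_dataset()] with classes `class1`/`class2` and
#'   attributes `deg_features` (ids of the informative genes) and `delta`
#'   (the drawn per-gene differences).
#' @export
simulate_case <- function(design) {
  if (!inherits(design, "simulation_design"))
    .stopf("design must be a simulation_design")
  npc <- design$n_per_class
  p <- design$p
  n <- 2L * npc
  delta_j <- if (length(design$delta) == 2L)
    stats::runif(design$n_deg, design$delta[1L], design$delta[2L])
  else rep(design$delta, design$n_deg)
  x <- matrix(stats::rnorm(n * p, mean = design$baseline_mean,
                           sd = sqrt(design$sigma_b2 + design$sigma_t2)),
              n, p)
  if (design$n_deg > 0L)
    x[seq_len(npc), seq_len(design$n_deg)] <-
      x[seq_len(npc), seq_len(design$n_deg)] +
      rep(delta_j, each = npc)
  labels <- rep(c("class1", "class2"), each = npc)
  ds <- expression_dataset(
    x, labels,
    sample_ids = sprintf("sample%03d", seq_len(n)),
    feature_ids = sprintf("gene%04d", seq_len(p)))
  attr(ds, "deg_features") <- ds$feature_ids[seq_len(design$n_deg)]
  attr(ds, "delta") <- delta_j
  ds
}

#' Condition indexes of the feature covariance
#'
#' kappa_k = sqrt(lambda_1 / lambda_k) for the k largest eigenvalues of the
#' gene-gene covariance matrix. When p > n the eigenvalues are obtained
#' through the n x n Gram matrix of the centered data (identical nonzero
#' spectrum) instead of forming the p x p covariance. A rapid increase over k
#' signals strong feature collinearity.
#'
#' @param x numeric matrix (samples x features) or an [expression_dataset()].
#' @param k how many indexes (5).
#' @return length-k numeric vector, first entry exactly 1; rank-deficient
#'   positions are reported as `Inf` with a warning.
#' @export
condition_indexes <- function(x, k = 5L) {
  if (inherits(x, "expression_dataset")) x <- x$x
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < k + 1L) .stopf("need at least k + 1 = %d samples", k + 1L)
  xc <- sweep(x, 2L, colMeans(x), "-")
  ev <- if (ncol(x) > n) {
    eigen(tcrossprod(xc) / (n - 1L), symmetric = TRUE, only.values = TRUE)$values
  } else {
    eigen(crossprod(xc) / (n - 1L), symmetric = TRUE, only.values = TRUE)$values
  }
  ev <- sort(ev, decreasing = TRUE)[seq_len(k)]
  tolv <- ev[1L] * 1e-12
  kap <- rep(Inf, k)
  ok <- ev > tolv
  kap[ok] <- sqrt(ev[1L] / ev[ok])
  if (any(!ok)) .warnf("rank deficiency: %d condition index(es) are infinite",
                       sum(!ok))
  kap
}

#' Principal-component / class-membership covariance diagnostics
#'
#' PCA of the centered matrix; for each of the first k principal components
#' the absolute covariance between its score vector and the signed class
#' vector (+1 first group, -1 second) is computed. Both the eigenvalues and
#' the covariances are scaled to their respective maxima, so relevant
#' components with small eigenvalues (a hard prediction problem) are easy to
#' spot.
#'
#' @param x numeric matrix (samples x features) or an [expression_dataset()]
#'   (in which case `labels` may be omitted).
#' @param labels two-level group labels.
#' @param k number of leading components (50; truncated to the achievable
#'   rank with a notice).
#' @return A `covariance_diagnostics` list: `condition_indexes` (first
#'   min(5, k)), `scaled_eigenvalues` and `class_covariances` (length k).
#' @export
pc_class_covariance <- function(x, labels = NULL, k = 50L) {
  if (inherits(x, "expression_dataset")) {
    if (is.null(labels)) labels <- x$labels
    x <- x$x
  }
  x <- as.matrix(x)
  n <- nrow(x)
  if (n <= 2L) .stopf("need more than 2 samples")
  dc <- dummy_code(labels)
  xc <- sweep(x, 2L, colMeans(x), "-")
  sv <- svd(xc, nu = min(n, ncol(x)), nv = 0L)
  rank <- sum(sv$d > sv$d[1L] * 1e-12)
  if (k > rank) {
    message(sprintf("rank is %d; truncating the series from %d", rank, k))
    k <- rank
  }
  scores <- sv$u[, seq_len(k), drop = FALSE] *
    rep(sv$d[seq_len(k)], each = n)
  ev <- sv$d[seq_len(k)]^2 / (n - 1L)
  cc <- dc$signed - mean(dc$signed)
  covs <- abs(drop(crossprod(scores, cc))) / (n - 1L)
  structure(list(
    condition_indexes = sqrt(ev[1L] / ev[seq_len(min(5L, k))]),
    scaled_eigenvalues = ev / ev[1L],
    class_covariances = if (max(covs) > 0) covs / max(covs) else covs),
    class = "covariance_diagnostics")
}

#' @export
print.covariance_diagnostics <- function(x, ...) {
  cat("covariance_diagnostics\n  condition indexes:",
      paste(formatC(x$condition_indexes, digits = 3, format = "f"),
            collapse = ", "),
      sprintf("\n  %d scaled eigenvalue/covariance pairs\n",
              length(x$scaled_eigenvalues)))
  invisible(x)
}
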