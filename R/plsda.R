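#' Between-group factor of a centered matrix
#'
#' The prior-weighted between-group sum of squares and cross-product matrix is
#' B = sum_g pi_g m_g m_g', with m_g the group mean rows of the centered
#' matrix. B is never formed in feature space: the function returns the small
#' g x p factor A with rows sqrt(pi_g) m_g, so that B = A'A and the dominant
#' eigenvector can be obtained from the g x g matrix A A'.
#'
#' @param xc column-centered numeric matrix (n x p).
#' @param dummy result of [dummy_code()] for the matching labels.
#' @param weights result of [sample_weights()].
#' @return list with `factor` (g x p) and `group_means` (g x p).
#' @export
between_group_factor <- function(xc, dummy, weights) {
  ng <- colSums(dummy$D)
  if (any(ng == 0)) .stopf("empty group in between_group_factor")
  gm <- crossprod(dummy$D, xc) / ng          # g x p group means
  list(factor = sqrt(weights$priors) * gm, group_means = gm)
}

#' Dominant discriminative direction from a between-group factor
#'
#' Solves the p x p eigenproblem of B = A'A through its g x g counterpart
#' A A', then back-transforms the dominant eigenvector to feature space and
#' normalises it. The sign is fixed by making the first entry larger than
#' 1e-12 in magnitude positive (eigenvectors are sign-ambiguous and the
#' downstream LDA is sign-invariant).
#'
#' @param bgf result of [between_group_factor()].
#' @return unit-norm numeric vector of length p.
#' @export
dominant_direction <- function(bgf) {
  A <- bgf$factor
  small <- tcrossprod(A)                      # g x g
  if (sum(small * small) < 1e-300)
    .stopf("no between-group variation: the group means coincide")
  e <- eigen(small, symmetric = TRUE)
  w <- unname(drop(crossprod(A, e$vectors[, 1L])))
  nw <- sqrt(sum(w * w))
  if (nw < 1e-150)
    .stopf("no between-group variation: the group means coincide")
  .fix_sign(w / nw)
}

## first entry with |w| > 1e-12 made positive
.fix_sign <- function(w) {
  i <- which(abs(w) > 1e-12)
  if (length(i) && w[i[1L]] < 0) -w else w
}

.new_projection_model <- function(weights, loadings, gamma, centering, scores,
                                  labels, priors, method) {
  rotation <- weights %*% solve(crossprod(loadings, weights))
  structure(list(weights = weights, loadings = loadings,
                 gamma_per_component = gamma, centering = centering,
                 n_components = ncol(weights), training_scores = scores,
                 rotation = rotation, labels = labels, priors = priors,
                 method = method),
            class = "projection_model")
}

#' @export
print.projection_model <- function(x, ...) {
  cat(sprintf("projection_model (%s): %d features, %d component(s), gamma = %s\n",
              x$method, nrow(x$weights), x$n_components,
              paste(formatC(x$gamma_per_component, digits = 3, format = "fg"),
                    collapse = ", ")))
  invisible(x)
}

.check_ncomp <- function(n_components, n, p, max_components = 5L) {
  n_components <- as.integer(n_components)
  if (length(n_components) != 1L || is.na(n_components) || n_components < 1L)
    .stopf("n_components must be a single integer >= 1")
  if (n_components > max_components)
    .stopf("n_components must be at most %d", max_components)
  hard <- min(n - 1L, p)
  if (n_components > hard)
    .stopf("requested %d components but at most %d are achievable for %d x %d data",
           n_components, hard, n, p)
  n_components
}

#' Fit a prior-weighted PLS-DA projection
#'
#' Sequential extraction of up to five latent components: each loading-weight
#' vector is the dominant eigenvector of the between-group matrix of the
#' current (deflated) data, the score is t = X w, the loading
#' p = X't / (t't), and X is deflated by t p'. Scores of successive
#' components are mutually orthogonal.
#'
#' @param data an [expression_dataset()].
#' @param priors prior specification passed to [sample_weights()].
#' @param n_components number of components, 1 to 5.
#' @return A `projection_model` with unit-norm weight columns, loadings,
#'   training scores, the centering vector, the training labels and a
#'   `gamma_per_component` vector fixed at 0.5 (the power value whose powered
#'   weights coincide with these covariance-based weights).
#' @export
fit_plsda <- function(data, priors = "empirical", n_components = 2L) {
  n_components <- .check_ncomp(n_components, nrow(data$x), ncol(data$x))
  ctr <- center_columns(data$x)
  dm <- dummy_code(data$labels)
  wts <- sample_weights(data$labels, priors)
  X <- ctr$x
  p <- ncol(X)
  W <- P <- matrix(0, p, n_components)
  Tm <- matrix(0, nrow(X), n_components)
  for (a in seq_len(n_components)) {
    bgf <- between_group_factor(X, dm, wts)
    w <- tryCatch(dominant_direction(bgf), error = function(e)
      .stopf("only %d component(s) achievable: %s", a - 1L, conditionMessage(e)))
    t_a <- drop(X %*% w)
    tt <- sum(t_a * t_a)
    if (tt < 1e-280)
      .stopf("only %d component(s) achievable: score collapsed to zero", a - 1L)
    p_a <- drop(crossprod(X, t_a)) / tt
    X <- X - tcrossprod(t_a, p_a)
    W[, a] <- w; P[, a] <- p_a; Tm[, a] <- t_a
  }
  .new_projection_model(W, P, gamma = rep(0.5, n_components),
                        centering = list(means = ctr$means),
                        scores = Tm, labels = data$labels, priors = priors,
                        method = "plsda")
}

#' Project new samples onto a fitted model
#'
#' Applies the stored training centering, then the rotation W (P'W)^-1, which
#' reproduces the sequential deflation exactly: projecting the training matrix
#' returns the stored training scores.
#'
#' @param model a `projection_model` from [fit_plsda()] or [fit_pplsda()].
#' @param newx numeric matrix (m x p) with the model's feature count, or an
#'   [expression_dataset()].
#' @return m x A score matrix.
#' @export
project <- function(model, newx) {
  if (inherits(newx, "expression_dataset")) newx <- newx$x
  newx <- as.matrix(newx)
  if (ncol(newx) != nrow(model$weights))
    .stopf("newx has %d columns but the model was fitted on %d features",
           ncol(newx), nrow(model$weights))
  apply_centering(newx, model$centering$means) %*% model$rotation
}

#' Serialize a projection model to a plain-text archive
#'
#' Writes every numeric field at full precision (hexadecimal float notation)
#' so [read_projection_model()] restores a bit-exact model.
#'
#' @param model a `projection_model`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_projection_model <- function(model, path) {
  num <- function(x) sprintf("%a", x)
  lines <- c(
    "pplsda_projection_model v1",
    paste0("method\t", model$method),
    paste0("n_components\t", model$n_components),
    paste0("priors\t", paste(if (is.character(model$priors)) model$priors
                             else num(model$priors), collapse = "\t")),
    paste0("gamma\t", paste(num(model$gamma_per_component), collapse = "\t")),
    paste0("centering\t", paste(num(model$centering$means), collapse = "\t")),
    paste0("labels\t", paste(as.character(model$labels), collapse = "\t")),
    paste0("weights\t", paste(num(model$weights), collapse = "\t")),
    paste0("loadings\t", paste(num(model$loadings), collapse = "\t")),
    paste0("scores\t", paste(num(model$training_scores), collapse = "\t")))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_projection_model
#' @export
read_projection_model <- function(path) {
  lines <- readLines(path)
  if (lines[1L] != "pplsda_projection_model v1")
    .stopf("%s is not a projection model archive", path)
  fld <- strsplit(lines[-1L], "\t", fixed = TRUE)
  names(fld) <- vapply(fld, `[[`, "", 1L)
  val <- lapply(fld, function(x) x[-1L])
  A <- as.integer(val$n_components)
  p <- length(val$centering)
  n <- length(val$labels)
  num <- function(x) as.numeric(x)
  .new_projection_model(
    weights = matrix(num(val$weights), p, A),
    loadings = matrix(num(val$loadings), p, A),
    gamma = num(val$gamma),
    centering = list(means = num(val$centering)),
    scores = matrix(num(val$scores), n, A),
    labels = factor(val$labels, levels = sort(unique(val$labels))),
    priors = if (identical(val$priors, "empirical")) "empirical"
             else num(val$priors),
    method = val$method)
}
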