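## Weighted column moments against the K-diagonal sample weighting.
## Returns per-feature sd and the correlation of each feature with each
## (weighted-centered) dummy column. With empirical priors the K diagonal is
## constant and these reduce to plain Pearson quantities.
.weighted_stats <- function(xc, dummy, weights) {
  v <- weights$weight_diagonal
  v <- v / sum(v)
  xm <- drop(crossprod(xc, v))
  x2 <- drop(crossprod(xc * xc, v))
  s2 <- pmax(x2 - xm * xm, 0)
  s <- sqrt(s2)
  ## deflation leaves O(1e-16) residue in extracted indicator columns; their
  ## correlation is scale-invariant, so they must count as zero-variance
  s[s < max(s) * 1e-9] <- 0
  Dc <- sweep(dummy$D, 2L, drop(crossprod(dummy$D, v)), "-")
  sdD <- sqrt(drop(crossprod(Dc * Dc, v)))
  cv <- crossprod(xc, v * Dc) - outer(xm, drop(crossprod(Dc, v)))
  rho <- cv / outer(s, sdD)
  rho[s == 0, ] <- 0
  list(s = s, rho = rho, v = v)
}

#' Powered candidate loading weights
#'
#' Column j of the candidate matrix W(gamma) combines, for every feature k,
#' the correlation part |rho_jk| and the standard-deviation part s_k as
#' sign(rho_jk) |rho_jk|^(gamma/(1-gamma)) s_k^((1-gamma)/gamma), normalised
#' to unit column norm. gamma = 0.5 gives both exponents 1 and the column is
#' collinear with the plain covariance weights; the endpoints degenerate to
#' indicator vectors: gamma = 0 selects the feature with the largest standard
#' deviation, gamma = 1 the feature with the largest absolute correlation
#' (ties broken to the lowest feature index). The powering is carried out in
#' log space so extreme exponents near the endpoints cannot overflow;
#' zero-variance features always receive weight 0.
#'
#' @param xc column-centered matrix (n x p).
#' @param dummy result of [dummy_code()].
#' @param weights result of [sample_weights()].
#' @param gamma power parameter in \[0, 1\].
#' @return list with `gamma` and `matrix` (p x g candidate weights, unit-norm
#'   nonzero columns).
#' @export
candidate_weights <- function(xc, dummy, weights, gamma) {
  if (!is.numeric(gamma) || length(gamma) != 1L || is.na(gamma) ||
      gamma < 0 || gamma > 1)
    .stopf("gamma must be a single value in [0, 1]")
  st <- .weighted_stats(xc, dummy, weights)
  p <- length(st$s)
  g <- ncol(dummy$D)
  W <- matrix(0, p, g)
  sgn <- sign(st$rho)
  if (gamma == 0) {
    i <- which.max(st$s)                    # ties -> lowest index
    if (st$s[i] > 0)
      W[i, ] <- ifelse(sgn[i, ] == 0, 1, sgn[i, ])
  } else if (gamma == 1) {
    for (j in seq_len(g)) {
      i <- which.max(abs(st$rho[, j]))
      if (abs(st$rho[i, j]) > 0) W[i, j] <- sgn[i, j]
    }
  } else {
    e_rho <- gamma / (1 - gamma)
    e_s <- (1 - gamma) / gamma
    ls <- log(pmax(st$s, 1e-300))
    ok <- st$s > 0
    for (j in seq_len(g)) {
      lw <- e_rho * log(pmax(abs(st$rho[, j]), 1e-300)) + e_s * ls
      w <- numeric(p)
      if (any(ok)) w[ok] <- exp(lw[ok] - max(lw[ok])) * sgn[ok, j]
      W[, j] <- w
    }
  }
  nrm <- sqrt(colSums(W * W))
  nz <- nrm > 0
  W[, nz] <- sweep(W[, nz, drop = FALSE], 2L, nrm[nz], "/")
  list(gamma = gamma, matrix = W)
}

#' Canonical-correlation objective of a candidate projection
#'
#' Projects the data onto the g candidate weight columns, Z(gamma) = X W(gamma),
#' and computes the leading canonical correlation between the weighted-centered
#' Z block and the dummy block under the K sample weighting. The g x g
#' within-block matrices receive a 1e-10 * trace ridge so rank-deficient blocks
#' (the centered dummy block always has rank g - 1) stay invertible. For two
#' groups the value equals the weighted multiple correlation of the signed
#' class vector on the columns of Z.
#'
#' @inheritParams candidate_weights
#' @return list with `gamma`, `value` (in \[0, 1\]), and `combiner` (length-g
#'   canonical coefficients on the Z side, used as the mixing vector a of the
#'   final loading weight W(gamma) a).
#' @export
cca_objective <- function(xc, dummy, weights, gamma) {
  cw <- candidate_weights(xc, dummy, weights, gamma)
  Z <- xc %*% cw$matrix
  v <- weights$weight_diagonal
  v <- v / sum(v)
  if (all(abs(Z) < 1e-300)) {
    .warnf("candidate projection is identically zero at gamma = %g", gamma)
    return(list(gamma = gamma, value = 0, combiner = c(1, rep(0, ncol(Z) - 1L))))
  }
  Zc <- sweep(Z, 2L, drop(crossprod(Z, v)), "-")
  Dc <- sweep(dummy$D, 2L, drop(crossprod(dummy$D, v)), "-")
  Szz <- crossprod(Zc, v * Zc)
  Sdd <- crossprod(Dc, v * Dc)
  Szd <- crossprod(Zc, v * Dc)
  ridge <- function(S) S + diag(1e-10 * max(sum(diag(S)), 1e-300), nrow(S))
  Rz <- chol(ridge(Szz))
  Rd <- chol(ridge(Sdd))
  M <- backsolve(Rz, Szd, transpose = TRUE)      # Rz^-T Szd
  M <- t(backsolve(Rd, t(M), transpose = TRUE))  # ... Rd^-1
  sv <- svd(M)
  value <- min(max(sv$d[1L], 0), 1)
  combiner <- backsolve(Rz, sv$u[, 1L])
  list(gamma = gamma, value = value, combiner = drop(combiner))
}

#' Choose gamma by canonical-correlation maximisation
#'
#' The classical per-component rule: maximise [cca_objective()] over the open
#' interval by scalar optimisation (tolerance 1e-4), then compare the interior
#' optimum against the two endpoint indicator rules evaluated at gamma = 0 and
#' gamma = 1. Ties between the endpoints go to the smaller gamma, and the
#' interior optimum is preferred only when it beats both endpoints beyond
#' numerical tolerance. A numerically flat objective is reported as
#' `flat = TRUE` with gamma 0.5.
#'
#' @inheritParams candidate_weights
#' @param tol optimisation tolerance on gamma.
#' @return list with `gamma_cc`, `objective` and `flat`.
#' @export
optimize_gamma_cc <- function(xc, dummy, weights, tol = 1e-4) {
  f <- function(g) cca_objective(xc, dummy, weights, g)$value
  probe <- vapply(c(0, 0.25, 0.5, 0.75, 1), f, 0)
  if (max(probe) - min(probe) < 1e-12)
    return(list(gamma_cc = 0.5, objective = probe[3L], flat = TRUE))
  opt <- stats::optimize(f, interval = c(0, 1), maximum = TRUE, tol = tol)
  ## endpoints first (0 before 1, so an endpoint tie goes to the smaller
  ## gamma); the interior optimum must beat both beyond tolerance, otherwise
  ## a saturated objective (corr -> 1 near an endpoint) would displace the
  ## exact indicator solution
  cand_g <- c(0, 1, opt$maximum)
  cand_v <- c(probe[1L], probe[5L], opt$objective)
  best <- which(cand_v >= max(cand_v) - 1e-12)[1L]
  list(gamma_cc = cand_g[best], objective = cand_v[best], flat = FALSE)
}

## one powered component on the current deflated matrix: returns the final
## unit loading weight w = W(gamma) a and the gamma actually used
.ppls_component <- function(X, dm, wts, gamma) {
  if (identical(gamma, "cc")) gamma <- optimize_gamma_cc(X, dm, wts)$gamma_cc
  obj <- cca_objective(X, dm, wts, gamma)
  w <- drop(candidate_weights(X, dm, wts, gamma)$matrix %*% obj$combiner)
  nw <- sqrt(sum(w * w))
  if (nw < 1e-150) .stopf("powered loading weight collapsed to zero")
  list(w = .fix_sign(w / nw), gamma = gamma)
}

#' Fit a powered PLS-DA projection
#'
#' Like [fit_plsda()] but each component's loading weight is the canonical
#' combination of the powered candidate columns, w = W(gamma) a. The power
#' parameter is either fixed for all components (`gamma` numeric, e.g. a value
#' selected jointly with the component count by [select_gamma_pe()]) or
#' re-optimised per component by canonical-correlation maximisation on the
#' current deflated matrix (`gamma = "cc"`).
#'
#' @inheritParams fit_plsda
#' @param gamma `"cc"` or a single value in \[0, 1\] applied to every
#'   component.
#' @return A `projection_model`; `gamma_per_component` records the gamma used
#'   for each component.
#' @export
fit_pplsda <- function(data, priors = "empirical", n_components = 2L,
                       gamma = "cc") {
  if (!identical(gamma, "cc") &&
      (!is.numeric(gamma) || length(gamma) != 1L || gamma < 0 || gamma > 1))
    .stopf("gamma must be \"cc\" or a single value in [0, 1]")
  n_components <- .check_ncomp(n_components, nrow(data$x), ncol(data$x))
  ctr <- center_columns(data$x)
  dm <- dummy_code(data$labels)
  wts <- sample_weights(data$labels, priors)
  X <- ctr$x
  p <- ncol(X)
  W <- P <- matrix(0, p, n_components)
  Tm <- matrix(0, nrow(X), n_components)
  gam <- numeric(n_components)
  for (a in seq_len(n_components)) {
    cmp <- tryCatch(.ppls_component(X, dm, wts, gamma), error = function(e)
      .stopf("only %d component(s) achievable: %s", a - 1L, conditionMessage(e)))
    t_a <- drop(X %*% cmp$w)
    tt <- sum(t_a * t_a)
    if (tt < 1e-280)
      .stopf("only %d component(s) achievable: score collapsed to zero", a - 1L)
    p_a <- drop(crossprod(X, t_a)) / tt
    X <- X - tcrossprod(t_a, p_a)
    W[, a] <- cmp$w; P[, a] <- p_a; Tm[, a] <- t_a; gam[a] <- cmp$gamma
  }
  .new_projection_model(W, P, gamma = gam,
                        centering = list(means = ctr$means),
                        scores = Tm, labels = data$labels, priors = priors,
                        method = if (identical(gamma, "cc")) "pplsda-cc"
                                 else "pplsda-fixed")
}
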