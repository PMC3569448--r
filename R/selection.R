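#' Equidistant gamma grid
#'
#' @param step grid step; must divide 1 exactly (e.g. 0.1 gives the 11 values
#'   0, 0.1, ..., 1).
#' @return list with `step` and `values` (both endpoints included).
#' @export
gamma_grid <- function(step = 0.1) {
  if (!is.numeric(step) || length(step) != 1L || step <= 0 || step > 0.5)
    .stopf("step must be a single value in (0, 0.5]")
  k <- round(1 / step)
  if (abs(k * step - 1) > 1e-9)
    .stopf("step %g does not divide the interval [0, 1] evenly", step)
  list(step = step, values = seq(0, k) / k)
}

#' Stratified Monte-Carlo train/test split
#'
#' Draws, within each group, round(fraction * n_g) samples (rounding half away
#' from zero) into the training part without replacement; the rest form the
#' test part. Uses the caller's RNG stream, so a fixed seed reproduces the
#' split exactly.
#'
#' @param labels two-level group labels.
#' @param fraction training fraction (0.7 throughout the package).
#' @return list with sorted integer vectors `train` and `test`.
#' @export
mc_split <- function(labels, fraction = 0.7) {
  f <- factor(as.character(labels))
  if (nlevels(f) != 2L) .stopf("mc_split needs two groups")
  train <- integer(0)
  for (lv in levels(f)) {
    idx <- which(f == lv)
    k <- .round_half_up(fraction * length(idx))
    if (k < 1L || k >= length(idx))
      .stopf("group '%s' (size %d) is too small to stratify at fraction %g",
             lv, length(idx), fraction)
    train <- c(train, idx[sample.int(length(idx), k)])
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(f), train))
}

## draw q stratified inner splits, redrawing degenerate ones (a group absent
## from either part, or a training group too small for LDA); abort after 100
## consecutive failures. With resample = "replacement" (the default used by
## the selection rules) the training part of each 0.7/0.3 partition is
## additionally resampled with replacement, so a training sample can recur
## within a split while the test part stays an untouched 0.3 holdout.
.draw_splits <- function(labels, q, fraction = 0.7, resample = "replacement") {
  splits <- vector("list", q)
  i <- 1L
  fails <- 0L
  while (i <= q) {
    sp <- mc_split(labels, fraction)
    if (resample == "replacement")
      sp$train <- sort(sample(sp$train, length(sp$train), replace = TRUE))
    ok <- length(unique(labels[sp$train])) == 2L &&
      length(unique(labels[sp$test])) == 2L &&
      all(table(labels[sp$train]) >= 2L)
    if (ok) {
      splits[[i]] <- sp
      i <- i + 1L
      fails <- 0L
    } else {
      fails <- fails + 1L
      if (fails >= 100L) .stopf("100 consecutive degenerate inner splits")
    }
  }
  splits
}

## duplicate-tolerant subsetting for bootstrap training multisets
.subset_for_fit <- function(data, idx) {
  expression_dataset(data$x[idx, , drop = FALSE],
                     as.character(data$labels)[idx],
                     sample_ids = sprintf("s%d", seq_along(idx)),
                     feature_ids = data$feature_ids)
}

## PE tensor (n_gamma x q x max_components) via the compiled kernel
.inner_cv_cpp <- function(x, signed, splits, gammas, max_components) {
  tr <- vapply(splits, function(s) s$train, integer(length(splits[[1L]]$train)))
  te <- vapply(splits, function(s) s$test, integer(length(splits[[1L]]$test)))
  cpp_inner_cv(x, as.integer(signed > 0), tr - 1L, te - 1L,
               as.numeric(gammas), as.integer(max_components))
}

## same tensor through the plain-R fitting path (reference engine)
.inner_cv_r <- function(data, splits, gammas, max_components) {
  q <- length(splits)
  pe <- array(NA_real_, c(length(gammas), q, max_components))
  for (s in seq_len(q)) {
    tr <- .subset_for_fit(data, splits[[s]]$train)
    te_x <- data$x[splits[[s]]$test, , drop = FALSE]
    te_y <- data$labels[splits[[s]]$test]
    for (gi in seq_along(gammas)) {
      model <- fit_pplsda(tr, n_components = max_components,
                          gamma = gammas[gi])
      sc_te <- project(model, te_x)
      for (a in seq_len(max_components)) {
        pe[gi, s, a] <- .lda_pe(model$training_scores[, seq_len(a), drop = FALSE],
                                tr$labels,
                                sc_te[, seq_len(a), drop = FALSE], te_y)
      }
    }
  }
  pe
}

## selection rule over the |grid| x A mean-PE matrix: per gamma the best
## component count (exact ties -> fewest), then the minimum over the grid
## (ties -> smallest gamma)
.pick_min <- function(mean_pe) {
  per_gamma_a <- unname(apply(unname(mean_pe), 1L, which.min))
  per_gamma_pe <- mean_pe[cbind(seq_len(nrow(mean_pe)), per_gamma_a)]
  gi <- which(per_gamma_pe <= min(per_gamma_pe) + 1e-12)[1L]
  c(gi = gi, a = per_gamma_a[gi])
}

#' Joint selection of gamma and the component count by inner Monte-Carlo CV
#'
#' The prediction-optimised rule: for each gamma on the grid and each of q
#' independent stratified 0.7/0.3 splits of the (outer) training set, a
#' fixed-gamma powered PLS-DA model with `max_components` components is fitted
#' once on the inner training part and the LDA prediction error on the inner
#' test part is recorded for 1 up to `max_components` leading components
#' (fitting the full model once and truncating is exact, because deflation
#' makes every shorter fit a prefix of the longer one). Inner PEs are averaged
#' over the q splits; for each gamma the best component count is kept, and the
#' global minimum over the grid yields (gamma*, A*). Ties are resolved to the
#' smaller mean PE, then fewer components, then smaller gamma.
#'
#' @param outer_train an [expression_dataset()] (normally the balanced outer
#'   training set produced by [outer_split()]).
#' @param grid a [gamma_grid()].
#' @param q number of inner Monte-Carlo splits (the reference configuration
#'   uses 50).
#' @param max_components maximal component count (5).
#' @param engine `"cpp"` (compiled kernel, empirical priors) or `"r"`
#'   (reference implementation through [fit_pplsda()]); both produce the same
#'   tensor.
#' @param resample `"replacement"` (default: the training part of each inner
#'   partition is resampled with replacement, the cross-validation steps
#'   being conform to sampling with replacement) or `"partition"` (plain
#'   disjoint 0.7/0.3 splits).
#' @return An `inner_cv_result`: `pe_tensor` (|grid| x q x max_components),
#'   `mean_pe` (|grid| x max_components), `gamma_star`, `ncomp_star`,
#'   `achieved_mean_pe`, plus the grid and q used.
#' @export
select_gamma_pe <- function(outer_train, grid = gamma_grid(0.1), q = 50L,
                            max_components = 5L, engine = c("cpp", "r"),
                            resample = c("replacement", "partition")) {
  engine <- match.arg(engine)
  resample <- match.arg(resample)
  if (q < 2L) .stopf("q must be at least 2")
  max_components <- .check_ncomp(max_components, nrow(outer_train$x),
                                 ncol(outer_train$x))
  splits <- .draw_splits(outer_train$labels, q, resample = resample)
  gam <- grid$values
  pe <- if (engine == "cpp") {
    .inner_cv_cpp(outer_train$x, dummy_code(outer_train$labels)$signed,
                  splits, gam, max_components)
  } else {
    .inner_cv_r(outer_train, splits, gam, max_components)
  }
  dimnames(pe) <- list(gamma = formatC(gam, format = "g"),
                       split = seq_len(q),
                       components = seq_len(max_components))
  mean_pe <- apply(pe, c(1L, 3L), mean)
  sel <- .pick_min(mean_pe)
  structure(list(pe_tensor = pe, mean_pe = mean_pe,
                 gamma_star = gam[sel["gi"]],
                 ncomp_star = as.integer(sel["a"]),
                 achieved_mean_pe = mean_pe[sel["gi"], sel["a"]],
                 grid = grid, q = q),
            class = "inner_cv_result")
}

#' @export
print.inner_cv_result <- function(x, ...) {
  cat(sprintf(
    "inner_cv_result: gamma* = %g, %d component(s), mean inner PE %.4f (q = %d)\n",
    x$gamma_star, x$ncomp_star, x$achieved_mean_pe, x$q))
  invisible(x)
}

#' Export the selection diagnostics as a table
#'
#' Long-format view of the mean inner prediction errors behind a selection,
#' convenient for histogram and trace reporting.
#'
#' @param result an `inner_cv_result`.
#' @return data.frame with columns gamma, n_components, mean_pe.
#' @export
selection_table <- function(result) {
  g <- result$grid$values
  A <- ncol(result$mean_pe)
  data.frame(gamma = rep(g, times = A),
             n_components = rep(seq_len(A), each = length(g)),
             mean_pe = as.vector(result$mean_pe))
}

#' Component-count selection by repeated Monte-Carlo CV
#'
#' The 10-repeat rule used for the methods whose gamma is not tuned for
#' prediction: mean LDA prediction error per component count over stratified
#' 0.7/0.3 splits of the training set, minimised over 1..`max_components`
#' (ties to the fewest components).
#'
#' @inheritParams select_gamma_pe
#' @param fit_method `"plsda"`, `"pplsda_cc"` (per-component
#'   canonical-correlation gamma) or `"pplsda_fixed"`.
#' @param gamma fixed power value, used when `fit_method = "pplsda_fixed"`.
#' @param repeats number of splits (10).
#' @return integer component count with attribute `mean_pe` (the per-count
#'   mean inner PEs).
#' @export
select_ncomp_cv <- function(outer_train,
                            fit_method = c("plsda", "pplsda_cc", "pplsda_fixed"),
                            gamma = 0.5, repeats = 10L, max_components = 5L,
                            engine = c("cpp", "r"),
                            resample = c("replacement", "partition")) {
  fit_method <- match.arg(fit_method)
  engine <- match.arg(engine)
  resample <- match.arg(resample)
  max_components <- .check_ncomp(max_components, nrow(outer_train$x),
                                 ncol(outer_train$x))
  splits <- .draw_splits(outer_train$labels, repeats, resample = resample)
  if (fit_method == "pplsda_cc") {
    pe <- matrix(NA_real_, repeats, max_components)
    for (s in seq_len(repeats)) {
      tr <- .subset_for_fit(outer_train, splits[[s]]$train)
      te_x <- outer_train$x[splits[[s]]$test, , drop = FALSE]
      te_y <- outer_train$labels[splits[[s]]$test]
      model <- fit_pplsda(tr, n_components = max_components, gamma = "cc")
      sc_te <- project(model, te_x)
      for (a in seq_len(max_components))
        pe[s, a] <- .lda_pe(model$training_scores[, seq_len(a), drop = FALSE],
                            tr$labels, sc_te[, seq_len(a), drop = FALSE], te_y)
    }
    mean_pe <- colMeans(pe)
  } else {
    ## PLS-DA weights coincide with the gamma = 0.5 powered weights for two
    ## groups, so both fixed-gamma methods share the same kernel
    g <- if (fit_method == "plsda") 0.5 else gamma
    tensor <- if (engine == "cpp") {
      .inner_cv_cpp(outer_train$x, dummy_code(outer_train$labels)$signed,
                    splits, g, max_components)
    } else {
      .inner_cv_r(outer_train, splits, g, max_components)
    }
    mean_pe <- apply(tensor, 3L, mean)
  }
  best <- which(mean_pe <= min(mean_pe) + 1e-12)[1L]   # ties -> fewest
  structure(as.integer(best), mean_pe = mean_pe)
}
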