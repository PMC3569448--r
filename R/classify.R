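#' Linear discriminant analysis on latent scores
#'
#' The terminal classifier of every PLS pipeline in this package: class means
#' plus a pooled within-class covariance on the (low-dimensional) component
#' scores. When the pooled covariance is ill-conditioned (condition number
#' above 1e12) a ridge of 1e-8 * trace / A is added. Priors default to the
#' empirical training proportions.
#'
#' @param scores n x A numeric score matrix.
#' @param labels two-level group labels (length n).
#' @param priors `"empirical"` or a length-2 nonnegative vector in sorted
#'   group order.
#' @return An `lda_model` with `class_means`, `pooled_covariance`,
#'   `cov_inverse`, `priors` and `class_order`.
#' @export
fit_lda <- function(scores, labels, priors = "empirical") {
  scores <- as.matrix(scores)
  dc <- dummy_code(labels)
  ng <- colSums(dc$D)
  if (any(ng < 2L)) .stopf("each group needs at least 2 samples for LDA")
  n <- nrow(scores)
  A <- ncol(scores)
  mu <- crossprod(dc$D, scores) / ng                 # g x A
  resid <- scores - mu[ifelse(dc$signed > 0, 1L, 2L), , drop = FALSE]
  Sw <- crossprod(resid) / (n - 2L)
  Sw <- (Sw + t(Sw)) / 2
  ev <- eigen(Sw, symmetric = TRUE, only.values = TRUE)$values
  if (ev[1L] <= 0 || ev[A] <= 0 || ev[1L] / ev[A] > 1e12)
    Sw <- Sw + diag(1e-8 * max(sum(diag(Sw)), 1e-300) / A, A)
  Si <- tryCatch(solve(Sw), error = function(e)
    .stopf("pooled covariance is singular even after ridging"))
  pr <- if (identical(priors, "empirical")) ng / n else {
    pr <- as.numeric(priors)
    if (length(pr) != 2L || any(pr < 0) || sum(pr) <= 0)
      .stopf("priors must be 2 nonnegative values")
    pr / sum(pr)
  }
  names(pr) <- dc$levels
  structure(list(class_means = mu, pooled_covariance = Sw, cov_inverse = Si,
                 priors = pr, class_order = dc$levels),
            class = "lda_model")
}

#' Predict group labels from an LDA model
#'
#' Assigns the class maximising the linear discriminant score
#' x' S^-1 mu_g - mu_g' S^-1 mu_g / 2 + log pi_g; exact ties are broken
#' deterministically to the first entry of `class_order`.
#'
#' @param model an [fit_lda()] model.
#' @param scores m x A matrix on the same score space.
#' @return character vector of predicted labels.
#' @export
predict_lda <- function(model, scores) {
  scores <- as.matrix(scores)
  if (ncol(scores) != ncol(model$class_means))
    .stopf("scores have %d columns but the model expects %d",
           ncol(scores), ncol(model$class_means))
  G <- model$cov_inverse %*% t(model$class_means)       # A x g
  const <- -0.5 * colSums(t(model$class_means) * G) + log(model$priors)
  delta <- sweep(scores %*% G, 2L, const, "+")
  model$class_order[max.col(delta, ties.method = "first")]
}

## fast internal path used inside cross-validation loops (g = 2)
.lda_pe <- function(train_scores, train_labels, test_scores, test_labels) {
  m <- fit_lda(train_scores, train_labels)
  mean(predict_lda(m, test_scores) != as.character(test_labels))
}

#' Proportion of wrongly classified samples
#'
#' @param predicted,truth label vectors of equal length.
#' @return misclassification proportion in \[0, 1\].
#' @export
prediction_error <- function(predicted, truth) {
  if (length(predicted) != length(truth))
    .stopf("predicted and truth differ in length (%d vs %d)",
           length(predicted), length(truth))
  if (length(truth) < 1L) .stopf("empty label vectors")
  mean(as.character(predicted) != as.character(truth))
}

## vectorised two-sample t-test p-values over the columns of x
.t_test_pvalues <- function(x, labels, var_equal = FALSE) {
  dc <- dummy_code(labels)
  g1 <- dc$signed > 0
  n1 <- sum(g1); n2 <- sum(!g1)
  m1 <- colMeans(x[g1, , drop = FALSE])
  m2 <- colMeans(x[!g1, , drop = FALSE])
  v1 <- colSums(sweep(x[g1, , drop = FALSE], 2L, m1, "-")^2) / (n1 - 1L)
  v2 <- colSums(sweep(x[!g1, , drop = FALSE], 2L, m2, "-")^2) / (n2 - 1L)
  if (var_equal) {
    sp2 <- ((n1 - 1L) * v1 + (n2 - 1L) * v2) / (n1 + n2 - 2L)
    se2 <- sp2 * (1 / n1 + 1 / n2)
    df <- rep(n1 + n2 - 2L, length(se2))
  } else {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / (v1^2 / (n1^2 * (n1 - 1L)) + v2^2 / (n2^2 * (n2 - 1L)))
  }
  tstat <- (m1 - m2) / sqrt(se2)
  pv <- 2 * stats::pt(-abs(tstat), df)
  pv[!is.finite(pv)] <- 1                  # zero-variance, zero-difference
  pv
}

#' t-test-filtered LDA baseline
#'
#' Ranks every feature by the p-value of a two-sample t-test computed on the
#' training set only, keeps the `n_features` smallest, and classifies the test
#' set with an LDA in that reduced feature space.
#'
#' @param train,test [expression_dataset()] objects sharing the same feature
#'   set (the outer training and outer test set).
#' @param n_features number of retained features (10 by default).
#' @param var_equal use the pooled-variance t-test instead of the
#'   unequal-variance (Welch) default.
#' @return list with `pe` (test prediction error), `features` (selected
#'   feature ids) and `p_values` (their training p-values).
#' @export
t_lda <- function(train, test, n_features = 10L, var_equal = FALSE) {
  if (!identical(train$feature_ids, test$feature_ids))
    .stopf("train and test feature sets differ")
  p <- ncol(train$x)
  if (p < n_features) {
    .warnf("only %d features available; using all of them", p)
    n_features <- p
  }
  pv <- .t_test_pvalues(train$x, train$labels, var_equal = var_equal)
  sel <- order(pv, seq_along(pv))[seq_len(n_features)]   # stable under ties
  m <- fit_lda(train$x[, sel, drop = FALSE], train$labels)
  pred <- predict_lda(m, test$x[, sel, drop = FALSE])
  list(pe = prediction_error(pred, test$labels),
       features = train$feature_ids[sel], p_values = pv[sel])
}

#' Linear-kernel SVM baseline (wrapper)
#'
#' A thin wrapper around the e1071 support vector machine: the cost parameter
#' of the linear kernel is tuned on the training set by k-fold
#' cross-validation over a logarithmic grid, the model is refitted at the best
#' cost and evaluated on the test set. This baseline is optional: when e1071
#' is not installed the call returns `pe = NA` with a notice instead of
#' failing.
#'
#' @inheritParams t_lda
#' @param cost_grid candidate cost values (default: 7 log-spaced points from
#'   1e-3 to 1e2).
#' @param folds number of cross-validation folds for the tuning (10).
#' @return list with `pe`, `cost` (tuned value) and `skipped`.
#' @export
svm_linear <- function(train, test,
                       cost_grid = 10^seq(-3, 2, length.out = 7L),
                       folds = 10L) {
  if (!requireNamespace("e1071", quietly = TRUE)) {
    message("svm_linear skipped: package 'e1071' is not installed")
    return(list(pe = NA_real_, cost = NA_real_, skipped = TRUE))
  }
  y <- factor(as.character(train$labels))
  tuned <- e1071::tune.svm(x = train$x, y = y, kernel = "linear",
                           cost = cost_grid, scale = FALSE,
                           tunecontrol = e1071::tune.control(cross = folds))
  cost <- tuned$best.parameters$cost
  fit <- e1071::svm(x = train$x, y = y, kernel = "linear", cost = cost,
                    scale = FALSE)
  pred <- as.character(predict(fit, test$x))
  list(pe = prediction_error(pred, test$labels), cost = cost, skipped = FALSE)
}
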