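#' Balanced outer train/test split with majority down-sampling
#'
#' Both groups contribute the same number of training samples,
#' round(0.7 * n_min) with n_min the minority group size (majority samples
#' beyond that are down-sampled away from the training set); every remaining
#' sample, from both groups, goes to the test set.
#'
#' @param data an [expression_dataset()].
#' @param train_per_class optional override of the per-group training size;
#'   `train_per_class = 30` reproduces the fixed 30 train / 30 test per class
#'   variant of the simulation study.
#' @return list with integer vectors `train` (balanced) and `test`.
#' @export
outer_split <- function(data, train_per_class = NULL) {
  f <- data$labels
  nmin <- min(table(f))
  if (nmin < 3L) .stopf("smallest group has %d samples; need at least 3", nmin)
  k <- if (is.null(train_per_class)) .round_half_up(0.7 * nmin)
       else as.integer(train_per_class)
  if (k < 2L || k >= nmin)
    .stopf("per-group training size %d is infeasible (minority group %d)",
           k, nmin)
  train <- integer(0)
  for (lv in levels(f)) {
    idx <- which(f == lv)
    train <- c(train, idx[sample.int(length(idx), k)])
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(f), train))
}

#' Student-t confidence interval for a mean prediction error
#'
#' mean +/- t_{1-alpha/2, R-1} * sd / sqrt(R), truncated to \[0, 1\].
#'
#' @param pe_vector numeric vector of per-repeat prediction errors (length
#'   >= 2; NAs from failed repeats are dropped with R adjusted).
#' @param level confidence level (0.95).
#' @return named numeric vector `c(lo, hi)`.
#' @export
confidence_interval <- function(pe_vector, level = 0.95) {
  x <- pe_vector[!is.na(pe_vector)]
  R <- length(x)
  if (R < 2L) .stopf("need at least 2 prediction errors, got %d", R)
  half <- stats::qt(1 - (1 - level) / 2, df = R - 1L) * stats::sd(x) / sqrt(R)
  c(lo = max(0, mean(x) - half), hi = min(1, mean(x) + half))
}

.methods_known <- c("pplsda_pe", "pplsda_cc", "pplsda_half", "plsda",
                    "t_lda", "svm")

## fit/select/predict for one method on one fixed outer split
.run_method <- function(method, train, test, q, grid, max_components,
                        svm_cost_grid) {
  pe <- NA_real_; gam <- NA_real_; nc <- NA_integer_
  if (method == "pplsda_pe") {
    sel <- select_gamma_pe(train, grid = grid, q = q,
                           max_components = max_components)
    model <- fit_pplsda(train, n_components = sel$ncomp_star,
                        gamma = sel$gamma_star)
    gam <- sel$gamma_star; nc <- sel$ncomp_star
  } else if (method %in% c("pplsda_cc", "pplsda_half", "plsda")) {
    fm <- switch(method, pplsda_cc = "pplsda_cc", pplsda_half = "pplsda_fixed",
                 plsda = "plsda")
    nc <- select_ncomp_cv(train, fit_method = fm, gamma = 0.5,
                          max_components = max_components)
    model <- if (method == "plsda") fit_plsda(train, n_components = nc)
             else fit_pplsda(train, n_components = nc,
                             gamma = if (method == "pplsda_cc") "cc" else 0.5)
    gam <- model$gamma_per_component[1L]
  } else if (method == "t_lda") {
    return(list(pe = t_lda(train, test)$pe, gamma = NA_real_,
                ncomp = NA_integer_))
  } else if (method == "svm") {
    return(list(pe = svm_linear(train, test, cost_grid = svm_cost_grid)$pe,
                gamma = NA_real_, ncomp = NA_integer_))
  }
  ldam <- fit_lda(model$training_scores, train$labels)
  pred <- predict_lda(ldam, project(model, test$x))
  list(pe = prediction_error(pred, test$labels), gamma = gam, ncomp = nc)
}

#' Run the full outer evaluation experiment
#'
#' For each of `repeats` outer repetitions: obtain a dataset (a fresh
#' simulation when `input` is a [simulation_design()], otherwise the given
#' dataset), draw one balanced outer split shared by every method, run each
#' method's hyperparameter selection on the outer training set only, refit on
#' the full outer training set and record the outer-test prediction error.
#' Randomness is fully determined by `base_seed`: the seed of each repeat is
#' drawn up front from `base_seed`, and within a repeat a single derived seed
#' re-initialises the stream before every method, so all methods consume
#' identical inner cross-validation segments. A repeat in which a
#' method fails is recorded as NA for that method, logged, and excluded from
#' the aggregation (never silently dropped).
#'
#' @param input a [simulation_design()] (fresh dataset per repeat) or an
#'   [expression_dataset()] (fresh split per repeat).
#' @param methods subset of `"pplsda_pe"`, `"pplsda_cc"`, `"pplsda_half"`,
#'   `"plsda"`, `"t_lda"`, `"svm"`.
#' @param repeats number of outer repetitions (reference configuration: 100).
#' @param q inner Monte-Carlo splits for the joint gamma selection (50).
#' @param grid_step gamma grid step (0.1).
#' @param max_components component cap (5).
#' @param base_seed integer master seed.
#' @param train_per_class passed to [outer_split()].
#' @param svm_cost_grid cost grid for the SVM baseline.
#' @param progress print one line per repeat.
#' @return An `outer_evaluation` with per-repeat `pe`, `gamma`, `ncomp`
#'   matrices (repeats x methods), the per-repeat seeds, and a character log
#'   of failures. Summarise with [summary.outer_evaluation()] and
#'   [compare_methods()].
#' @export
run_experiment <- function(input, methods = c("pplsda_pe", "pplsda_cc"),
                           repeats = 100L, q = 50L, grid_step = 0.1,
                           max_components = 5L, base_seed = 1L,
                           train_per_class = NULL,
                           svm_cost_grid = 10^seq(-3, 2, length.out = 7L),
                           progress = FALSE) {
  if (length(methods) < 1L) .stopf("methods must be nonempty")
  bad <- setdiff(methods, .methods_known)
  if (length(bad)) .stopf("unknown method '%s'", bad[1L])
  if (repeats < 1L) .stopf("repeats must be >= 1")
  is_design <- inherits(input, "simulation_design")
  if (!is_design && !inherits(input, "expression_dataset"))
    .stopf("input must be a simulation_design or an expression_dataset")
  grid <- gamma_grid(grid_step)

  set.seed(base_seed)
  repeat_seeds <- sample.int(.Machine$integer.max - 1L, repeats)

  M <- length(methods)
  pe <- gam <- matrix(NA_real_, repeats, M, dimnames = list(NULL, methods))
  nc <- matrix(NA_integer_, repeats, M, dimnames = list(NULL, methods))
  split_fp <- character(repeats)
  log <- character(0)

  for (r in seq_len(repeats)) {
    set.seed(repeat_seeds[r])
    data <- if (is_design) simulate_case(input) else input
    sp <- outer_split(data, train_per_class = train_per_class)
    split_fp[r] <- paste(sp$train, collapse = ",")
    train <- subset_samples(data, sp$train)
    test <- subset_samples(data, sp$test)
    ## one shared seed per repeat: every method re-seeds with it, so all
    ## methods consume identical inner cross-validation segments
    inner_seed <- sample.int(.Machine$integer.max - 1L, 1L)
    for (m in seq_len(M)) {
      set.seed(inner_seed)
      res <- tryCatch(
        .run_method(methods[m], train, test, q, grid, max_components,
                    svm_cost_grid),
        error = function(e) {
          log <<- c(log, sprintf("repeat %d, method %s failed: %s",
                                 r, methods[m], conditionMessage(e)))
          list(pe = NA_real_, gamma = NA_real_, ncomp = NA_integer_)
        })
      pe[r, m] <- res$pe
      gam[r, m] <- res$gamma
      nc[r, m] <- res$ncomp
    }
    if (progress)
      message(sprintf("repeat %d/%d: %s", r, repeats,
                      paste(sprintf("%s=%.3f", methods, pe[r, ]),
                            collapse = " ")))
  }
  structure(list(pe = pe, gamma = gam, ncomp = nc, methods = methods,
                 repeats = repeats, repeat_seeds = repeat_seeds,
                 split_fingerprints = split_fp, failures = log,
                 q = q, grid_step = grid_step, base_seed = base_seed),
            class = "outer_evaluation")
}

#' Summarise an outer evaluation
#'
#' @param object an `outer_evaluation`.
#' @param level confidence level for the mean-PE intervals.
#' @param ... unused.
#' @return data.frame with one row per method: mean PE, CI bounds, mean
#'   selected gamma and component count, and the number of successful repeats.
#' @export
summary.outer_evaluation <- function(object, level = 0.95, ...) {
  rows <- lapply(seq_along(object$methods), function(m) {
    x <- object$pe[, m]
    ci <- confidence_interval(x, level)
    data.frame(method = object$methods[m],
               mean_pe = mean(x, na.rm = TRUE),
               ci_lo = ci[["lo"]], ci_hi = ci[["hi"]],
               mean_gamma = mean(object$gamma[, m], na.rm = TRUE),
               mean_ncomp = mean(object$ncomp[, m], na.rm = TRUE),
               n_ok = sum(!is.na(x)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @export
print.outer_evaluation <- function(x, ...) {
  cat(sprintf("outer_evaluation: %d repeat(s), methods %s\n",
              x$repeats, paste(x$methods, collapse = ", ")))
  print(summary(x), row.names = FALSE)
  if (length(x$failures))
    cat(sprintf("%d failed method-repeat(s); see $failures\n",
                length(x$failures)))
  invisible(x)
}

#' Pairwise significance by confidence-interval overlap
#'
#' Two methods are called significantly different when their mean-PE
#' confidence intervals are disjoint, and not significantly different when
#' the intervals overlap.
#'
#' @param evaluation an `outer_evaluation`.
#' @param level confidence level (0.95).
#' @return symmetric logical matrix (TRUE = significantly different) with a
#'   FALSE diagonal.
#' @export
compare_methods <- function(evaluation, level = 0.95) {
  M <- length(evaluation$methods)
  if (M < 2L) .stopf("need at least 2 methods to compare")
  ci <- vapply(seq_len(M),
               function(m) confidence_interval(evaluation$pe[, m], level),
               numeric(2L))
  sig <- matrix(FALSE, M, M,
                dimnames = list(evaluation$methods, evaluation$methods))
  for (i in seq_len(M - 1L)) {
    for (j in seq(i + 1L, M)) {
      disjoint <- ci["hi", i] < ci["lo", j] || ci["hi", j] < ci["lo", i]
      sig[i, j] <- sig[j, i] <- disjoint
    }
  }
  sig
}
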