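#' Construct a validated two-group expression dataset
#'
#' The basic container used throughout the package: a numeric samples x
#' features matrix (log-scale expression values) together with a two-level
#' group label per sample. Validation enforces the contracts every downstream
#' fit relies on: finite entries, exactly two groups with at least two samples
#' each, at least four samples and two features, unique identifiers.
#'
#' @param x numeric matrix, samples in rows, features in columns.
#' @param labels vector of group labels, one per row of `x`; must take exactly
#'   two distinct values. Stored as a factor with lexicographically sorted
#'   levels; the first level is coded +1 in the signed response.
#' @param sample_ids,feature_ids optional unique identifier vectors; default
#'   to the dimnames of `x` or generated `sample##`/`feature##` names.
#' @return An object of class `expression_dataset` with elements `x`,
#'   `labels`, `sample_ids`, `feature_ids`.
#' @examples
#' d <- expression_dataset(matrix(rnorm(40), 8, 5), rep(c("a", "b"), each = 4))
#' d
#' @export
expression_dataset <- function(x, labels, sample_ids = NULL, feature_ids = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  n <- nrow(x)
  p <- ncol(x)
  if (length(labels) != n)
    .stopf("labels has length %d but the matrix has %d rows", length(labels), n)
  if (!all(is.finite(x))) {
    bad <- which(!is.finite(x), arr.ind = TRUE)[1L, ]
    .stopf("non-finite entry at row %d, column %d", bad[1L], bad[2L])
  }
  if (n < 4L) .stopf("need at least 4 samples, got %d", n)
  if (p < 2L) .stopf("need at least 2 features, got %d", p)
  lv <- sort(unique(as.character(labels)))
  if (length(lv) != 2L)
    .stopf("labels must have exactly 2 levels, got %d (%s)",
           length(lv), paste(utils::head(lv, 5L), collapse = ", "))
  f <- factor(as.character(labels), levels = lv)
  if (any(table(f) < 2L)) .stopf("each group needs at least 2 samples")
  if (is.null(sample_ids)) sample_ids <- rownames(x)
  if (is.null(sample_ids) || !all(nzchar(sample_ids)))
    sample_ids <- sprintf("sample%0*d", nchar(n), seq_len(n))
  if (is.null(feature_ids)) feature_ids <- colnames(x)
  if (is.null(feature_ids) || !all(nzchar(feature_ids)))
    feature_ids <- sprintf("feature%0*d", nchar(p), seq_len(p))
  sample_ids <- as.character(sample_ids)
  feature_ids <- as.character(feature_ids)
  if (anyDuplicated(sample_ids))
    .stopf("duplicate sample id: %s", sample_ids[duplicated(sample_ids)][1L])
  if (anyDuplicated(feature_ids))
    .stopf("duplicate feature id: %s", feature_ids[duplicated(feature_ids)][1L])
  dimnames(x) <- list(sample_ids, feature_ids)
  structure(list(x = x, labels = f, sample_ids = sample_ids,
                 feature_ids = feature_ids),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  tab <- table(x$labels)
  cat(sprintf("expression_dataset: %d samples x %d features; groups %s (%s)\n",
              nrow(x$x), ncol(x$x),
              paste(names(tab), collapse = "/"),
              paste(tab, collapse = "/")))
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$x)

#' Subset an expression dataset by sample
#'
#' @param data an [expression_dataset()].
#' @param idx integer or logical sample index.
#' @return A validated `expression_dataset` restricted to `idx`.
#' @export
subset_samples <- function(data, idx) {
  expression_dataset(data$x[idx, , drop = FALSE],
                     as.character(data$labels)[idx],
                     sample_ids = data$sample_ids[idx],
                     feature_ids = data$feature_ids)
}

.sniff_sep <- function(path) {
  line <- readLines(path, n = 1L)
  if (grepl("\t", line)) "\t" else ","
}

#' Read a delimited expression table as a dataset
#'
#' Reads a tab- or comma-delimited numeric table with a header row and an
#' identifier column (the first column), normalises it to samples x features,
#' and attaches the group labels, which may live in a designated column of the
#' table or in a separate two-column id -> label file.
#'
#' @param path path of the delimited matrix file.
#' @param label_source either the name of a column of the table holding the
#'   group label, or the path of a two-column delimited file mapping sample id
#'   to label.
#' @param samples_in_rows logical; set `FALSE` when the file stores features
#'   in rows and samples in columns (the table is then transposed and labels
#'   must come from a companion file keyed by the column names).
#' @param sep field delimiter; by default auto-detected among tab and comma.
#' @return An [expression_dataset()].
#' @export
load_dataset <- function(path, label_source, samples_in_rows = TRUE, sep = NULL) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  if (is.null(sep)) sep <- .sniff_sep(path)
  tab <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                           stringsAsFactors = FALSE, comment.char = "",
                           quote = "\"")
  if (ncol(tab) < 2L) .stopf("table in %s has fewer than 2 columns", path)
  ids <- as.character(tab[[1L]])
  tab <- tab[, -1L, drop = FALSE]

  labels <- NULL
  if (length(label_source) == 1L && label_source %in% colnames(tab)) {
    labels <- as.character(tab[[label_source]])
    tab <- tab[, setdiff(colnames(tab), label_source), drop = FALSE]
  }

  ## every remaining cell must be numeric and non-missing
  for (j in seq_along(tab)) {
    col <- tab[[j]]
    if (!is.numeric(col)) {
      suppressWarnings(num <- as.numeric(col))
      bad <- which(is.na(num) & !is.na(col))
      if (length(bad) == 0L) bad <- which(is.na(col))
      .stopf("non-numeric cell in row %d, column '%s'", bad[1L], colnames(tab)[j])
    }
    if (anyNA(col))
      .stopf("missing value in row %d, column '%s'",
             which(is.na(col))[1L], colnames(tab)[j])
  }
  m <- as.matrix(tab)
  rownames(m) <- ids

  if (!samples_in_rows) m <- t(m)

  if (is.null(labels)) {
    if (!file.exists(label_source))
      .stopf("label_source '%s' is neither a column of the table nor a file",
             label_source)
    lsep <- .sniff_sep(label_source)
    lt <- utils::read.table(label_source, header = TRUE, sep = lsep,
                            check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(lt) < 2L) .stopf("label file %s needs two columns", label_source)
    key <- as.character(lt[[1L]])
    if (!all(rownames(m) %in% key))
      .stopf("label file %s is missing sample '%s'", label_source,
             setdiff(rownames(m), key)[1L])
    labels <- as.character(lt[[2L]])[match(rownames(m), key)]
  }
  expression_dataset(m, labels, sample_ids = rownames(m),
                     feature_ids = colnames(m))
}

#' Write a dataset as a delimited table
#'
#' Inverse of [load_dataset()]: writes sample ids, a label column and the
#' expression matrix into one delimited file so datasets round-trip
#' losslessly.
#'
#' @param data an [expression_dataset()].
#' @param path output path.
#' @param label_column name of the label column written into the table.
#' @param sep delimiter, tab by default.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(data, path, label_column = "class", sep = "\t") {
  if (label_column %in% data$feature_ids)
    .stopf("label_column '%s' collides with a feature id", label_column)
  df <- data.frame(sample_id = data$sample_ids,
                   lab = as.character(data$labels),
                   data$x, check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df)[2L] <- label_column
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Dummy-code a two-level group vector
#'
#' Builds the n x 2 indicator matrix D (entry 1 when the sample belongs to the
#' group, 0 otherwise) and the signed class vector (+1 for the first group in
#' lexicographic order, -1 for the second).
#'
#' @param labels a two-level label vector or factor.
#' @return A list with `D` (n x 2, columns named by group), `signed`
#'   (+1/-1 vector) and `levels` (sorted group symbols).
#' @export
dummy_code <- function(labels) {
  lv <- sort(unique(as.character(labels)))
  if (length(lv) != 2L)
    .stopf("dummy coding requires exactly 2 label levels, got %d", length(lv))
  f <- factor(as.character(labels), levels = lv)
  n <- length(f)
  D <- matrix(0, n, 2L, dimnames = list(NULL, lv))
  D[cbind(seq_len(n), as.integer(f))] <- 1
  list(D = D, signed = ifelse(as.integer(f) == 1L, 1, -1), levels = lv)
}

#' Column-center a matrix, keeping the centering vector
#'
#' @param x numeric matrix.
#' @return list with `x` (centered matrix) and `means` (column means, to be
#'   reapplied to held-out data via [apply_centering()]).
#' @export
center_columns <- function(x) {
  x <- as.matrix(x)
  mu <- colMeans(x)
  list(x = sweep(x, 2L, mu, "-"), means = mu)
}

#' Apply a stored centering vector to new rows
#'
#' @param x numeric matrix with the same number of columns as the training
#'   matrix the centering was computed on.
#' @param means the `means` element returned by [center_columns()].
#' @export
apply_centering <- function(x, means) {
  x <- as.matrix(x)
  if (ncol(x) != length(means))
    .stopf("matrix has %d columns but centering vector has length %d",
           ncol(x), length(means))
  sweep(x, 2L, means, "-")
}

#' Prior-based sample weights
#'
#' The diagonal weighting matrix K attached to a grouped sample: the entry for
#' sample i equals pi_g / (n_g * n), the prior probability of its group
#' divided by the group size times the total number of samples. With empirical
#' priors pi_g = n_g / n this is the constant 1 / n^2, so the default
#' weighting is a no-op for every fit.
#'
#' @param labels two-level group labels.
#' @param priors `"empirical"` (group proportions, the default) or a length-2
#'   nonnegative numeric vector in sorted-group order; normalised to sum 1.
#' @return list with `priors` (named, sums to 1), `weight_diagonal` (length-n
#'   positive vector) and `levels`.
#' @export
sample_weights <- function(labels, priors = "empirical") {
  dc <- dummy_code(labels)
  ng <- colSums(dc$D)
  n <- nrow(dc$D)
  if (identical(priors, "empirical")) {
    pr <- ng / n
  } else {
    pr <- as.numeric(priors)
    if (length(pr) != 2L) .stopf("priors must have length 2")
    if (any(pr < 0)) .stopf("priors must be nonnegative")
    if (sum(pr) <= 0) .stopf("priors must not all be zero")
    pr <- pr / sum(pr)
  }
  names(pr) <- dc$levels
  g <- ifelse(dc$signed > 0, 1L, 2L)
  list(priors = pr, weight_diagonal = pr[g] / (ng[g] * n), levels = dc$levels)
}
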