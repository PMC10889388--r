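# Feature-table cleaning, scaling and selection.
#
# The isolation forest is implemented in-package (random partition trees on
# subsamples of 256 rows, anomaly score 2^(-E[h]/c(psi))); cleaning is
# applied per class batch, mirroring how seed batches are curated
# separately. Scaling is the median/IQR robust scaler with type-7
# (linearly interpolated) quartiles. All five selectors return subsets of
# the feature column names.

feature_columns <- function(df) {
  cols <- intersect(FEATURE_NAMES, colnames(df))
  if (!length(cols)) cols <- setdiff(colnames(df), "label")
  cols
}

as_feature_matrix <- function(df, cols = feature_columns(df)) {
  as.matrix(df[, cols, drop = FALSE])
}

# -- isolation forest --------------------------------------------------------

# average unsuccessful-search path length in a BST of n nodes
iforest_c <- function(n) {
  if (n <= 1) return(0)
  2 * (log(n - 1) + 0.5772156649) - 2 * (n - 1) / n
}

iforest_build <- function(x, depth_limit, seed) {
  with_seed(seed, {
    build <- function(rows, depth) {
      n <- length(rows)
      if (n <= 1L || depth >= depth_limit)
        return(list(leaf = TRUE, size = n))
      j <- sample.int(ncol(x), 1L)
      lo <- min(x[rows, j]); hi <- max(x[rows, j])
      if (lo == hi) return(list(leaf = TRUE, size = n))
      s <- stats::runif(1, lo, hi)
      left <- rows[x[rows, j] < s]
      right <- rows[x[rows, j] >= s]
      list(leaf = FALSE, feature = j, split = s,
           left = build(left, depth + 1L), right = build(right, depth + 1L))
    }
    build(seq_len(nrow(x)), 0L)
  })
}

iforest_depths <- function(tree, x, rows, depth = 0) {
  if (tree$leaf)
    return(rep(depth + iforest_c(tree$size), length(rows)))
  go_left <- x[rows, tree$feature] < tree$split
  out <- numeric(length(rows))
  if (any(go_left))
    out[go_left] <- iforest_depths(tree$left, x, rows[go_left], depth + 1)
  if (any(!go_left))
    out[!go_left] <- iforest_depths(tree$right, x, rows[!go_left], depth + 1)
  out
}

#' Isolation-forest anomaly scores
#'
#' Standard isolation forest: `n_trees` random partition trees, each grown
#' on a random subsample of `sample_size` rows to depth `ceiling(log2
#' (sample_size))`; the score of a row is `2^(-E[h]/c(psi))` where `E[h]` is
#' its average path length and `c(psi)` the expected path length of an
#' unsuccessful search. Scores near 1 are anomalous.
#'
#' @param x Numeric matrix (rows = observations).
#' @param n_trees Number of trees (default 100).
#' @param sample_size Subsample size per tree (default 256, capped at n).
#' @param rng_seed Integer seed.
#' @return Numeric vector of anomaly scores in (0, 1).
#' @export
isolation_scores <- function(x, n_trees = 100L, sample_size = 256L,
                             rng_seed = 1L) {
  x <- as.matrix(x)
  n <- nrow(x)
  psi <- min(as.integer(sample_size), n)
  depth_limit <- ceiling(log2(max(2, psi)))
  paths <- matrix(0, n, n_trees)
  for (t in seq_len(n_trees)) {
    st <- derive_seed(rng_seed, t)
    sub <- with_seed(derive_seed(st, 1L), sample.int(n, psi))
    tree <- iforest_build(x[sub, , drop = FALSE], depth_limit,
                          derive_seed(st, 2L))
    paths[, t] <- iforest_depths(tree, x, seq_len(n))
  }
  2^(-rowMeans(paths) / iforest_c(psi))
}

#' Flag outlier rows of a feature table
#'
#' Scores rows with an isolation forest and flags the most anomalous
#' fraction `contamination`, independently within each class batch when a
#' `label` column is present (batches are curated separately). With
#' contamination 0 nothing is flagged.
#'
#' @param table Feature `data.frame` (optionally with a `label` column).
#' @param contamination Expected anomalous fraction, in `[0, 0.5)`.
#' @param rng_seed Integer seed.
#' @param by_class Clean per class batch (default `TRUE` when labels exist).
#' @return Logical keep-mask (`TRUE` = retain the row).
#' @export
flag_outliers <- function(table, contamination = 0.05, rng_seed = 1L,
                          by_class = TRUE) {
  if (contamination < 0 || contamination >= 0.5)
    stop("contamination must lie in [0, 0.5)")
  x <- as_feature_matrix(table)
  n <- nrow(x)
  keep <- rep(TRUE, n)
  if (contamination == 0) return(keep)
  batches <- if (by_class && "label" %in% colnames(table))
    split(seq_len(n), table$label, drop = TRUE)
  else list(all = seq_len(n))
  for (bi in seq_along(batches)) {
    rows <- batches[[bi]]
    if (!length(rows)) next
    sc <- isolation_scores(x[rows, , drop = FALSE],
                           rng_seed = derive_seed(rng_seed, bi))
    k <- round(contamination * length(rows))
    if (k > 0L) {
      flagged <- order(sc, decreasing = TRUE)[seq_len(k)]
      keep[rows[flagged]] <- FALSE
    }
  }
  keep
}

# -- robust scaling ----------------------------------------------------------

#' Fit a robust (median/IQR) scaler
#'
#' Per-column median and interquartile range `Q3 - Q1`, quartiles by linear
#' interpolation. Columns with zero IQR get scale 1 so constant columns map
#' to zero rather than NaN.
#'
#' @param table Feature `data.frame` or matrix (training rows only).
#' @return List of class `"robust_scaler"` with `center`, `scale`, `columns`.
#' @export
fit_robust_scaler <- function(table) {
  cols <- feature_columns(as.data.frame(table))
  x <- as_feature_matrix(as.data.frame(table), cols)
  if (nrow(x) == 0L) stop("empty table")
  center <- apply(x, 2L, stats::median)
  q <- apply(x, 2L, stats::quantile, probs = c(0.25, 0.75), names = FALSE)
  scale <- q[2L, ] - q[1L, ]
  scale[scale == 0] <- 1
  structure(list(center = center, scale = scale, columns = cols),
            class = "robust_scaler")
}

#' Apply a fitted robust scaler
#'
#' @param table Feature `data.frame` (train or test partition).
#' @param params A `"robust_scaler"` from [fit_robust_scaler()].
#' @return The table with scaled feature columns; other columns untouched.
#' @export
apply_robust_scaler <- function(table, params) {
  stopifnot(inherits(params, "robust_scaler"))
  out <- as.data.frame(table)
  for (j in seq_along(params$columns)) {
    cn <- params$columns[j]
    out[[cn]] <- (out[[cn]] - params$center[j]) / params$scale[j]
  }
  out
}

# -- feature selection -------------------------------------------------------

#' Variance-threshold selection
#'
#' Keeps columns whose sample variance exceeds `threshold` (default 0.02,
#' the production setting on robust-scaled data).
#'
#' @param table Feature `data.frame`.
#' @param threshold Variance threshold.
#' @return Character vector of kept column names.
#' @export
select_variance <- function(table, threshold = 0.02) {
  x <- as_feature_matrix(table)
  v <- apply(x, 2L, stats::var)
  colnames(x)[v > threshold]
}

#' Chi-squared top-k selection
#'
#' Shifts each column to be non-negative (subtracting its minimum), computes
#' the chi-squared statistic of per-class column sums against the
#' class-frequency expectation, and keeps the `k` highest-scoring columns
#' (default k = 5, the production setting).
#'
#' @param table Feature `data.frame` with a `label` column.
#' @param k Number of columns to keep.
#' @return Character vector of `k` kept column names, in original column
#'   order.
#' @export
select_chi2 <- function(table, k = 5L) {
  x <- as_feature_matrix(table)
  if (k > ncol(x)) stop("k exceeds the number of feature columns")
  g <- factor(table$label)
  x <- sweep(x, 2L, apply(x, 2L, min))  # non-negativity shift
  y <- stats::model.matrix(~ g - 1)  # one-hot classes
  observed <- t(y) %*% x                      # class x feature sums
  class_prob <- colMeans(y)
  feature_tot <- colSums(x)
  expected <- outer(class_prob, feature_tot)
  chi2 <- colSums((observed - expected)^2 / ifelse(expected > 0, expected, 1))
  chi2[feature_tot == 0] <- 0
  keep <- order(chi2, decreasing = TRUE)[seq_len(k)]
  colnames(x)[sort(keep)]
}

#' Model-importance selection via a linear hinge-loss classifier
#'
#' Fits the package's stochastic-gradient-descent hinge classifier
#' (one-vs-rest) and keeps columns whose importance - the mean over classes
#' of the absolute coefficient - is at least the mean importance across
#' columns (the "mean" threshold rule).
#'
#' @param table Feature `data.frame` with a `label` column (>= 2 classes).
#' @param rng_seed Integer seed for the SGD sweep order.
#' @param alpha L2 regularization strength of the SGD fit.
#' @return Character vector of kept column names.
#' @export
select_model_importance <- function(table, rng_seed = 1L, alpha = 1e-4) {
  g <- factor(table$label)
  if (nlevels(droplevels(g)) < 2L) stop("need at least 2 classes")
  x <- as_feature_matrix(table)
  fit <- sgd_hinge_fit(x, droplevels(g), alpha = alpha, rng_seed = rng_seed)
  importance <- colMeans(abs(fit$w))
  colnames(x)[importance >= mean(importance)]
}

#' Recursive feature elimination with cross-validation
#'
#' Per fold, iteratively drops the lowest-importance column (linear
#' hinge-classifier importance) and records validation accuracy at every
#' column count; the count with the best mean accuracy wins (ties go to the
#' smaller count), and a final elimination pass on the full table returns
#' that many columns.
#'
#' @param table Feature `data.frame` with a `label` column.
#' @param cv_folds Number of folds (rows must be >= folds).
#' @param rng_seed Integer seed.
#' @return Character vector of kept column names.
#' @export
select_rfecv <- function(table, cv_folds = 5L, rng_seed = 1L) {
  g <- droplevels(factor(table$label))
  x <- as_feature_matrix(table)
  n <- nrow(x); p <- ncol(x)
  if (n < cv_folds) stop("fewer rows than folds")
  folds <- with_seed(derive_seed(rng_seed, 0L),
                     sample(rep(seq_len(cv_folds), length.out = n)))
  # rfe_path: order in which columns are dropped, given training rows
  rfe_path <- function(rows, seed) {
    active <- seq_len(p)
    dropped <- integer(0)
    counter <- 0L
    while (length(active) > 1L) {
      counter <- counter + 1L
      fit <- sgd_hinge_fit(x[rows, active, drop = FALSE], g[rows],
                           rng_seed = derive_seed(seed, counter))
      imp <- colMeans(abs(fit$w))
      worst <- active[which.min(imp)]
      dropped <- c(dropped, worst)
      active <- setdiff(active, worst)
    }
    c(dropped, active)  # drop order; last survivor at the end
  }
  acc <- matrix(NA_real_, cv_folds, p)  # accuracy by (fold, n_features)
  for (f in seq_len(cv_folds)) {
    tr <- which(folds != f); va <- which(folds == f)
    path <- rfe_path(tr, derive_seed(rng_seed, f))
    for (m in seq_len(p)) {
      active <- path[(p - m + 1L):p]  # the m columns dropped last
      fit <- sgd_hinge_fit(x[tr, active, drop = FALSE], g[tr],
                           rng_seed = derive_seed(rng_seed, 1000L + f * p + m))
      pred <- sgd_hinge_predict(fit, x[va, active, drop = FALSE])
      acc[f, m] <- mean(pred == g[va])
    }
  }
  mean_acc <- colMeans(acc)
  best_m <- which(mean_acc >= max(mean_acc) - 1e-12)[1L]  # ties -> fewer
  final_path <- rfe_path(seq_len(n), derive_seed(rng_seed, 999983L))
  keep <- sort(final_path[(p - best_m + 1L):p])
  colnames(x)[keep]
}

#' ANOVA F-test selection
#'
#' One-way F-test of each column across the classes; keeps columns with
#' `p < alpha` (default 0.05). No multiplicity correction is applied.
#'
#' @param table Feature `data.frame` with a `label` column (>= 2 classes,
#'   >= 2 rows per class).
#' @param alpha Significance level.
#' @return Character vector of kept column names.
#' @export
select_anova <- function(table, alpha = 0.05) {
  g <- droplevels(factor(table$label))
  if (nlevels(g) < 2L) stop("need at least 2 classes")
  if (any(table(g) < 2L)) stop("need at least 2 rows per class")
  x <- as_feature_matrix(table)
  pvals <- apply(x, 2L, function(col) {
    if (stats::var(col) == 0) return(1)
    stats::oneway.test(col ~ g, var.equal = TRUE)$p.value
  })
  colnames(x)[!is.na(pvals) & pvals < alpha]
}
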