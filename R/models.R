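# Train/test splitting, the four classifiers (KN, SGD, SVM, RF), grid
# search, evaluation metrics and learning curves.
#
# KN, SVM and RF delegate to class::knn, e1071::svm and
# randomForest::randomForest; the linear hinge-loss SGD classifier is
# implemented in-package (Pegasos-style one-vs-rest) because it also powers
# the model-importance and RFECV feature selectors.

MODEL_NAMES <- c(kn = "KN", sgd = "SGD", svm = "SVM", rf = "RF")

# -- splitting ---------------------------------------------------------------

#' Stratified train/test split
#'
#' Disjoint, exhaustive partition with `ceiling(n * test_fraction)` test
#' rows. Under stratification the test quota is apportioned to classes by
#' largest remainder, keeping per-class proportions within one row.
#'
#' @param table Feature `data.frame` with a `label` column.
#' @param test_fraction Fraction held out for testing (default 0.2).
#' @param stratified Stratify by class (default `TRUE`).
#' @param rng_seed Integer seed.
#' @return List with `train` and `test` data frames.
#' @export
split_train_test <- function(table, test_fraction = 0.2, stratified = TRUE,
                             rng_seed = 42L) {
  n <- nrow(table)
  if (n < 5L) stop("need at least 5 rows")
  if (test_fraction <= 0 || test_fraction >= 1)
    stop("test_fraction must lie in (0, 1)")
  n_test <- as.integer(ceiling(n * test_fraction))
  test_idx <- with_seed(rng_seed, {
    if (!stratified) {
      sample.int(n, n_test)
    } else {
      g <- factor(table$label)
      counts <- table(g)
      if (any(counts < 2L))
        stop("every class needs >= 2 rows for a stratified split")
      quota <- counts * test_fraction
      base <- floor(quota)
      rem <- n_test - sum(base)
      if (rem > 0L) {
        extra <- order(quota - base, decreasing = TRUE)[seq_len(rem)]
        base[extra] <- base[extra] + 1L
      } else if (rem < 0L) {
        cut <- order(quota - base)[seq_len(-rem)]
        base[cut] <- base[cut] - 1L
      }
      unlist(lapply(seq_along(levels(g)), function(ci) {
        rows <- which(g == levels(g)[ci])
        sample(rows, base[ci])
      }), use.names = FALSE)
    }
  })
  list(train = table[-test_idx, , drop = FALSE],
       test = table[test_idx, , drop = FALSE])
}

# -- SGD hinge classifier ----------------------------------------------------

# Pegasos-style SGD on the regularized hinge loss, one-vs-rest. The
# intercept rides along as an appended constant feature; eta_t =
# 1/(alpha * t); weights averaged over the final epoch for stability.
sgd_hinge_fit <- function(x, y, alpha = 1e-4, epochs = 20L, rng_seed = 1L) {
  x <- cbind(as.matrix(x), `(bias)` = 1)
  y <- droplevels(factor(y))
  classes <- levels(y)
  n <- nrow(x); p <- ncol(x)
  w <- matrix(0, length(classes), p)
  for (ci in seq_along(classes)) {
    target <- ifelse(y == classes[ci], 1, -1)
    wi <- numeric(p)
    t <- 0
    w_acc <- numeric(p); n_acc <- 0L
    for (ep in seq_len(epochs)) {
      ord <- with_seed(derive_seed(rng_seed, ci * 1000L + ep), sample.int(n))
      for (i in ord) {
        t <- t + 1
        eta <- 1 / (alpha * t)
        margin <- target[i] * sum(wi * x[i, ])
        wi <- wi * (1 - eta * alpha)
        if (margin < 1) wi <- wi + eta * target[i] * x[i, ]
        if (ep == epochs) {
          w_acc <- w_acc + wi; n_acc <- n_acc + 1L
        }
      }
    }
    w[ci, ] <- w_acc / n_acc
  }
  structure(list(w = w[, -p, drop = FALSE], b = w[, p],
                 classes = classes, alpha = alpha),
            class = "sgd_hinge")
}

sgd_hinge_predict <- function(fit, x) {
  x <- as.matrix(x)
  scores <- x %*% t(fit$w) + matrix(fit$b, nrow(x), length(fit$b),
                                    byrow = TRUE)
  factor(fit$classes[max.col(scores, ties.method = "first")],
         levels = fit$classes)
}

# -- unified fit/predict -----------------------------------------------------

# gamma = "scale" heuristic: 1 / (p * var(all x))
gamma_scale <- function(x) 1 / (ncol(x) * stats::var(as.vector(as.matrix(x))))

#' Fit one of the four models and predict test labels
#'
#' Model contracts: `"kn"` is the majority vote of the k nearest training
#' rows by Euclidean distance; `"sgd"` a linear hinge-loss classifier fitted
#' by stochastic gradient descent; `"svm"` a kernel maximum-margin
#' classifier; `"rf"` bagged randomized decision trees. Seeded models are
#' deterministic given `rng_seed`.
#'
#' @param model One of `"kn"`, `"sgd"`, `"svm"`, `"rf"` (case-insensitive).
#' @param params Named list of hyper-parameters: `k` (kn); `alpha` (sgd);
#'   `kernel`, `cost`, `gamma` (svm; `gamma = "scale"` uses the
#'   `1/(p * var)` heuristic); `ntree`, `max_depth` (rf; `max_depth = NA`
#'   grows full trees).
#' @param train,test Feature data frames sharing columns; `train` must have
#'   a `label` column covering all classes.
#' @param rng_seed Integer seed.
#' @return Factor of predicted test labels.
#' @export
train_predict <- function(model, params, train, test, rng_seed = 1L) {
  model <- tolower(model)
  model <- match.arg(model, names(MODEL_NAMES))
  cols <- feature_columns(train)
  if (!all(cols %in% colnames(test)))
    stop("test table lacks training feature columns")
  xtr <- as_feature_matrix(train, cols)
  xte <- as_feature_matrix(test, cols)
  ytr <- droplevels(factor(train$label))
  with_seed(rng_seed, {
    switch(model,
      kn = {
        k <- params$k %||% 5L
        class::knn(xtr, xte, ytr, k = k)
      },
      sgd = {
        fit <- sgd_hinge_fit(xtr, ytr, alpha = params$alpha %||% 1e-4,
                             rng_seed = rng_seed)
        sgd_hinge_predict(fit, xte)
      },
      svm = {
        gam <- params$gamma %||% "scale"
        if (identical(gam, "scale")) gam <- gamma_scale(xtr)
        fit <- e1071::svm(xtr, ytr, kernel = params$kernel %||% "radial",
                          cost = params$cost %||% 1, gamma = gam,
                          scale = FALSE)
        stats::predict(fit, xte)
      },
      rf = {
        depth <- params$max_depth
        nodesize <- 1L
        maxnodes <- if (is.null(depth) || is.na(depth)) NULL
                    else as.integer(min(2^depth, nrow(xtr)))
        randomForest::randomForest(
          xtr, ytr, ntree = params$ntree %||% 100L,
          nodesize = nodesize, maxnodes = maxnodes
        ) |> stats::predict(xte)
      }
    )
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default hyper-parameter grids for the four models
#'
#' @return Named list of data frames, one grid row per candidate.
#' @export
model_grids <- function() {
  list(
    kn = data.frame(k = c(3L, 5L, 7L, 11L)),
    sgd = data.frame(alpha = c(1e-4, 1e-3, 1e-2)),
    svm = expand.grid(kernel = c("linear", "radial"),
                      cost = c(0.1, 1, 10, 100),
                      gamma = c("scale", "0.01", "0.1"),
                      KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE),
    rf = expand.grid(ntree = c(100L, 300L), max_depth = c(NA, 10L, 20L),
                     KEEP.OUT.ATTRS = FALSE)
  )
}

grid_row_params <- function(grid, i) {
  pr <- as.list(grid[i, , drop = FALSE])
  pr <- lapply(pr, function(v) if (is.factor(v)) as.character(v) else v)
  if (!is.null(pr$gamma) && !identical(pr$gamma, "scale"))
    pr$gamma <- as.numeric(pr$gamma)
  pr
}

#' Exhaustive grid search with k-fold cross-validation
#'
#' Evaluates every grid row by stratified-free k-fold CV mean accuracy on
#' the training partition only; the best mean accuracy wins, ties going to
#' the first row in grid order.
#'
#' @param model Model name (see [train_predict()]).
#' @param train Training `data.frame` with a `label` column.
#' @param cv_folds Number of folds (>= 2).
#' @param grid Data frame of candidate hyper-parameters (defaults to
#'   [model_grids()]).
#' @param rng_seed Integer seed (fold assignment and model fits).
#' @return List with `params` (best row as a list), `cv_accuracy`, and
#'   `results` (the grid with a `cv_accuracy` column).
#' @export
grid_search <- function(model, train, cv_folds = 5L, grid = NULL,
                        rng_seed = 1L) {
  model <- tolower(model)
  if (is.null(grid)) grid <- model_grids()[[model]]
  if (is.null(grid) || nrow(grid) == 0L) stop("empty hyper-parameter grid")
  if (cv_folds < 2L) stop("cv_folds must be >= 2")
  n <- nrow(train)
  folds <- with_seed(derive_seed(rng_seed, 0L),
                     sample(rep(seq_len(cv_folds), length.out = n)))
  accs <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    pr <- grid_row_params(grid, i)
    fold_acc <- vapply(seq_len(cv_folds), function(f) {
      tr <- train[folds != f, , drop = FALSE]
      va <- train[folds == f, , drop = FALSE]
      pred <- train_predict(model, pr, tr, va,
                            rng_seed = derive_seed(rng_seed, i * 100L + f))
      mean(as.character(pred) == as.character(va$label))
    }, 0)
    accs[i] <- mean(fold_acc)
  }
  best <- which.max(accs)  # ties -> first in grid order
  out <- grid
  out$cv_accuracy <- accs
  list(params = grid_row_params(grid, best), cv_accuracy = accs[best],
       results = out)
}

# -- evaluation --------------------------------------------------------------

#' Evaluate predictions against true labels
#'
#' Builds the confusion matrix (rows = true, cols = predicted, fixed class
#' order), per-class precision and recall, macro averages, the macro F1
#' from the per-class harmonic means, and accuracy. A class never predicted
#' gets precision 0 (and analogously recall for an absent class).
#'
#' @param truth,predicted Equal-length label vectors drawn from `classes`.
#' @param classes Class order (default [SEED_CLASSES]).
#' @param model Optional model display name stored in the report.
#' @return Object of class `"eval_report"`.
#' @export
evaluate <- function(truth, predicted, classes = SEED_CLASSES,
                     model = NULL) {
  truth <- as.character(truth); predicted <- as.character(predicted)
  if (length(truth) != length(predicted))
    stop("label vectors differ in length")
  if (!all(truth %in% classes) || !all(predicted %in% classes))
    stop("label outside the class set")
  tf <- factor(truth, levels = classes)
  pf <- factor(predicted, levels = classes)
  cm <- table(truth = tf, predicted = pf)
  cm <- matrix(as.integer(cm), nrow = length(classes),
               dimnames = list(truth = classes, predicted = classes))
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  precision <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  recall <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  structure(list(
    model = model,
    accuracy = sum(tp) / sum(cm),
    macro_precision = mean(precision),
    macro_recall = mean(recall),
    macro_f1 = mean(f1),
    per_class = data.frame(class = classes, precision = precision,
                           recall = recall, f1 = f1, support = rowSums(cm),
                           row.names = NULL),
    confusion = cm
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, digits = 3, ...) {
  cat(sprintf("<eval_report>%s n = %d\n",
              if (!is.null(x$model)) paste0(" model: ", x$model, ","),
              sum(x$confusion)))
  cat(sprintf("  accuracy %.3f | macro precision %.3f | recall %.3f | F1 %.3f\n",
              x$accuracy, x$macro_precision, x$macro_recall, x$macro_f1))
  cat("  confusion (rows = truth):\n")
  print(x$confusion)
  invisible(x)
}

#' Learning curve of a model
#'
#' For each requested training size, k-fold cross-validation where the model
#' is fitted on the first `size` rows of the (seed-shuffled) training part
#' of each fold; reports mean train and validation accuracy per size.
#'
#' @param model Model name.
#' @param params Hyper-parameter list (see [train_predict()]).
#' @param table Feature `data.frame` with labels.
#' @param train_sizes Ascending vector of training-set sizes.
#' @param cv_folds Number of folds.
#' @param rng_seed Integer seed.
#' @return List of class `"learning_curve"` with `train_sizes`,
#'   `train_scores`, `validation_scores`.
#' @export
learning_curve <- function(model, params, table, train_sizes,
                           cv_folds = 5L, rng_seed = 1L) {
  if (is.unsorted(train_sizes)) stop("train_sizes must be ascending")
  n <- nrow(table)
  folds <- with_seed(derive_seed(rng_seed, 0L),
                     sample(rep(seq_len(cv_folds), length.out = n)))
  if (max(train_sizes) > n - max(table(folds)))
    stop("largest train size exceeds the training rows available per fold")
  tr_sc <- va_sc <- matrix(NA_real_, cv_folds, length(train_sizes))
  for (f in seq_len(cv_folds)) {
    tr_rows <- which(folds != f)
    va <- table[folds == f, , drop = FALSE]
    shuffled <- with_seed(derive_seed(rng_seed, 100L + f), sample(tr_rows))
    for (s in seq_along(train_sizes)) {
      sz <- train_sizes[s]
      sub <- table[shuffled[seq_len(sz)], , drop = FALSE]
      if (nlevels(droplevels(factor(sub$label))) < 1L) next
      seed_fs <- derive_seed(rng_seed, 200L + f * length(train_sizes) + s)
      pred_va <- train_predict(model, params, sub, va, rng_seed = seed_fs)
      pred_tr <- train_predict(model, params, sub, sub, rng_seed = seed_fs)
      va_sc[f, s] <- mean(as.character(pred_va) == as.character(va$label))
      tr_sc[f, s] <- mean(as.character(pred_tr) == as.character(sub$label))
    }
  }
  structure(list(train_sizes = train_sizes,
                 train_scores = colMeans(tr_sc, na.rm = TRUE),
                 validation_scores = colMeans(va_sc, na.rm = TRUE)),
            class = "learning_curve")
}

#' @export
plot.learning_curve <- function(x, main = "Learning curve", ...) {
  graphics::plot(x$train_sizes, x$train_scores, type = "b", pch = 19,
                 ylim = range(c(x$train_scores, x$validation_scores)),
                 xlab = "training rows", ylab = "accuracy", main = main, ...)
  graphics::lines(x$train_sizes, x$validation_scores, type = "b", pch = 1,
                  lty = 2)
  graphics::legend("bottomright", c("train", "validation"),
                   pch = c(19, 1), lty = c(1, 2), bty = "n")
  invisible(x)
}
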