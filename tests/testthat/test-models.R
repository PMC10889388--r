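test_that("split sizes follow the ceiling rule", {
  ft <- sample_feature_table(c(PBP = 1335L, PBA = 1416L, PNP = 1437L,
                               PNA = 1430L), rng_seed = 1L)
  keep_n <- 5336L  # cleaned-table size whose 80/20 split is checked
  clean <- ft[seq_len(keep_n), , drop = FALSE]
  parts <- split_train_test(clean, 0.2, stratified = FALSE, rng_seed = 1L)
  expect_equal(nrow(parts$train), 4268L)
  expect_equal(nrow(parts$test), 1068L)
  small <- sample_feature_table(3L, rng_seed = 2L)[1:10, ]
  p2 <- split_train_test(small, 0.2, stratified = FALSE, rng_seed = 1L)
  expect_equal(c(nrow(p2$train), nrow(p2$test)), c(8L, 2L))
})

test_that("stratified splits keep class proportions within one row", {
  ft <- sample_feature_table(50L, rng_seed = 3L)
  parts <- split_train_test(ft, 0.2, stratified = TRUE, rng_seed = 4L)
  tt <- table(parts$test$label)
  expect_true(all(abs(tt - 50 * 0.2) <= 1))
  expect_equal(nrow(parts$train) + nrow(parts$test), nrow(ft))
  expect_equal(length(intersect(rownames(parts$train),
                                rownames(parts$test))), 0L)
  # deterministic given the seed
  parts2 <- split_train_test(ft, 0.2, stratified = TRUE, rng_seed = 4L)
  expect_identical(rownames(parts$test), rownames(parts2$test))
})

test_that("grid search returns the argmax over its grid", {
  ft <- sample_feature_table(40L, class_shift = 3, rng_seed = 5L)
  one <- grid_search("kn", ft, cv_folds = 3L,
                     grid = data.frame(k = 7L), rng_seed = 1L)
  expect_equal(one$params$k, 7L)
  gs <- grid_search("kn", ft, cv_folds = 3L, rng_seed = 1L)
  expect_equal(gs$cv_accuracy, max(gs$results$cv_accuracy))
  expect_gte(gs$cv_accuracy, max(gs$results$cv_accuracy) - 1e-12)
  expect_error(grid_search("kn", ft, grid = data.frame()), "empty")
})

test_that("all four models exceed 0.9 CV accuracy on a separable table", {
  ft <- sample_feature_table(40L, class_shift = 8, rng_seed = 6L)
  sc <- fit_robust_scaler(ft)
  ft_s <- apply_robust_scaler(ft, sc)
  for (m in c("kn", "sgd", "svm", "rf")) {
    gs <- grid_search(m, ft_s, cv_folds = 3L, rng_seed = 2L)
    expect_gt(gs$cv_accuracy, 0.9)
  }
})

test_that("1-nearest-neighbour memorizes its training set", {
  ft <- sample_feature_table(15L, rng_seed = 7L)
  pred <- train_predict("kn", list(k = 1L), ft, ft, rng_seed = 1L)
  expect_equal(as.character(pred), as.character(ft$label))
})

test_that("models agree with the nearest-centroid rule on a wide-margin toy", {
  set.seed(8)
  mk <- function(n) {
    mu <- list(PBP = c(0, 0), PBA = c(20, 0), PNP = c(0, 20),
               PNA = c(20, 20))
    do.call(rbind, lapply(SEED_CLASSES, function(cl)
      data.frame(area = stats::rnorm(n, mu[[cl]][1]),
                 width = stats::rnorm(n, mu[[cl]][2]),
                 label = factor(cl, levels = SEED_CLASSES))))
  }
  train <- mk(20L); test <- mk(10L)
  centroids <- sapply(SEED_CLASSES, function(cl)
    colMeans(train[train$label == cl, 1:2]))
  nc <- SEED_CLASSES[apply(as.matrix(test[, 1:2]), 1L, function(r)
    which.min(colSums((centroids - r)^2)))]
  params <- list(kn = list(k = 5L), sgd = list(alpha = 1e-3),
                 svm = list(kernel = "linear", cost = 1, gamma = "scale"),
                 rf = list(ntree = 100L, max_depth = NA))
  for (m in names(params)) {
    pred <- train_predict(m, params[[m]], train, test, rng_seed = 3L)
    expect_equal(as.character(pred), nc)
  }
})

test_that("KN and SVM are invariant to training-row order", {
  ft <- sample_feature_table(25L, class_shift = 3, rng_seed = 9L)
  test <- sample_feature_table(10L, class_shift = 3, rng_seed = 10L)
  set.seed(11)
  perm <- sample(nrow(ft))
  shuffled <- ft[perm, , drop = FALSE]
  for (m in c("kn", "svm")) {
    p1 <- train_predict(m, list(k = 5L, kernel = "radial", cost = 1,
                                gamma = "scale"), ft, test, rng_seed = 5L)
    p2 <- train_predict(m, list(k = 5L, kernel = "radial", cost = 1,
                                gamma = "scale"), shuffled, test,
                        rng_seed = 5L)
    expect_equal(as.character(p1), as.character(p2))
  }
})

test_that("evaluate reproduces brute-force counting on random labels", {
  set.seed(12)
  for (r in 1:10) {
    n <- sample(20:60, 1)
    truth <- sample(SEED_CLASSES, n, TRUE)
    pred <- sample(SEED_CLASSES, n, TRUE)
    ev <- evaluate(truth, pred)
    ref <- oracle_metrics(truth, pred, SEED_CLASSES)
    expect_equal(ev$accuracy, ref$accuracy)
    expect_equal(ev$macro_precision, ref$macro_precision)
    expect_equal(ev$macro_recall, ref$macro_recall)
    expect_equal(ev$macro_f1, ref$macro_f1)
    expect_equal(sum(ev$confusion), n)
    expect_equal(unname(rowSums(ev$confusion)),
                 unname(as.vector(table(factor(truth,
                                               levels = SEED_CLASSES)))))
  }
})

test_that("perfect predictions give unit metrics and a diagonal matrix", {
  truth <- rep(SEED_CLASSES, each = 5)
  ev <- evaluate(truth, truth)
  expect_equal(ev$accuracy, 1)
  expect_equal(ev$macro_f1, 1)
  expect_true(all(ev$confusion[upper.tri(ev$confusion)] == 0))
  expect_true(all(ev$confusion[lower.tri(ev$confusion)] == 0))
  expect_error(evaluate(truth, rep("XX", length(truth))), "class set")
})

test_that("per-class precision = recall = p implies per-class F1 = p", {
  # cyclic confusion: every class 8 correct, 2 sent to the next class
  truth <- rep(SEED_CLASSES, each = 10)
  pred <- truth
  for (i in seq_along(SEED_CLASSES)) {
    rows <- which(truth == SEED_CLASSES[i])[1:2]
    pred[rows] <- SEED_CLASSES[i %% 4 + 1]
  }
  ev <- evaluate(truth, pred)
  expect_equal(ev$per_class$precision, rep(0.8, 4))
  expect_equal(ev$per_class$recall, rep(0.8, 4))
  expect_equal(ev$per_class$f1, rep(0.8, 4))
  expect_equal(ev$macro_f1, 0.8)
})

test_that("evaluate is invariant to joint permutation of the pairs", {
  set.seed(13)
  truth <- sample(SEED_CLASSES, 40, TRUE)
  pred <- sample(SEED_CLASSES, 40, TRUE)
  perm <- sample(40)
  e1 <- evaluate(truth, pred)
  e2 <- evaluate(truth[perm], pred[perm])
  expect_equal(e1$confusion, e2$confusion)
  expect_equal(e1$macro_f1, e2$macro_f1)
})

test_that("learning curves have one entry per size and sane train scores", {
  ft <- sample_feature_table(30L, class_shift = 4, rng_seed = 14L)
  sizes <- c(20L, 40L, 80L)
  lc <- learning_curve("kn", list(k = 1L), ft, sizes, cv_folds = 3L,
                       rng_seed = 1L)
  expect_equal(length(lc$train_scores), 3L)
  expect_equal(length(lc$validation_scores), 3L)
  expect_equal(unname(lc$train_scores), rep(1, 3))  # 1-NN interpolates
  expect_error(learning_curve("kn", list(k = 1L), ft, c(10L, 1000L)),
               "exceeds")
})

test_that("validation accuracy grows with training size on separable data", {
  rhos <- vapply(1:10, function(s) {
    ft <- sample_feature_table(40L, class_shift = 1.5,
                               rng_seed = 4000L + s)
    lc <- learning_curve("kn", list(k = 5L), ft, c(16L, 40L, 80L, 120L),
                         cv_folds = 4L, rng_seed = s)
    stats::cor(lc$validation_scores, c(16, 40, 80, 120),
               method = "spearman")
  }, 0)
  expect_gt(mean(rhos), 0)
})
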