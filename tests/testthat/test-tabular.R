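test_that("robust scaler reproduces hand-computed quartiles", {
  df <- data.frame(area = 1:9)
  sc <- fit_robust_scaler(df)
  expect_equal(unname(sc$center), 5)
  expect_equal(unname(sc$scale), 4)  # Q3 - Q1 by linear interpolation
  scaled <- apply_robust_scaler(df, sc)
  expect_equal(scaled$area[9L], 1)
})

test_that("constant columns scale to zero via the IQR fallback", {
  df <- data.frame(area = rep(3, 10), width = 1:10)
  sc <- fit_robust_scaler(df)
  expect_equal(apply_robust_scaler(df, sc)$area, rep(0, 10))
})

test_that("scaled training data has median 0 and IQR 1", {
  ft <- sample_feature_table(50L, rng_seed = 2L)
  sc <- fit_robust_scaler(ft)
  scaled <- apply_robust_scaler(ft, sc)
  x <- as.matrix(scaled[, FEATURE_NAMES])
  expect_equal(max(abs(apply(x, 2L, stats::median))), 0, tolerance = 1e-12)
  iqr <- apply(x, 2L, function(v) diff(stats::quantile(v, c(0.25, 0.75))))
  expect_equal(unname(iqr), rep(1, 18), tolerance = 1e-12)
})

test_that("variance selector drops constants and matches brute force", {
  ft <- sample_feature_table(30L, rng_seed = 3L)
  ft$area <- 1  # constant
  kept <- select_variance(ft, threshold = 0)
  expect_false("area" %in% kept)
  expect_equal(length(kept), 17L)
  thr <- 0.5
  kept2 <- select_variance(ft, thr)
  brute <- FEATURE_NAMES[vapply(FEATURE_NAMES, function(cn)
    stats::var(ft[[cn]]) > thr, TRUE)]
  expect_identical(kept2, brute)
})

test_that("chi-squared selector keeps k columns and zeroes flat ones", {
  ft <- sample_feature_table(40L, rng_seed = 4L)
  expect_equal(length(select_chi2(ft, 5L)), 5L)
  expect_identical(sort(select_chi2(ft, 18L)), sort(FEATURE_NAMES))
  expect_error(select_chi2(ft, 19L), "exceeds")
  # a column identical for every row carries no class signal: never in top 5
  ft$area <- 42
  expect_false("area" %in% select_chi2(ft, 5L))
})

test_that("model-importance selection keeps real signal over noise", {
  set.seed(6)
  n <- 80L
  df <- as.data.frame(matrix(stats::rnorm(n * 18), n, 18))
  colnames(df) <- FEATURE_NAMES
  df$label <- factor(rep(c("PBP", "PNP"), each = n / 2),
                     levels = SEED_CLASSES)
  sep <- ifelse(df$label == "PBP", -3, 3) + stats::rnorm(n, 0, 0.1)
  df$area <- sep       # perfectly separating column
  df$width <- sep      # duplicated informative column
  kept <- select_model_importance(df, rng_seed = 1L)
  expect_true("area" %in% kept)
  expect_true(length(kept) >= 1L && length(kept) <= 18L)
  expect_error(select_model_importance(df[df$label == "PBP", ]), "classes")
})

test_that("RFECV keeps a perfect column and prefers fewer on ties", {
  set.seed(7)
  n <- 60L
  df <- as.data.frame(matrix(stats::rnorm(n * 6), n, 6))
  colnames(df) <- FEATURE_NAMES[1:6]
  df$label <- factor(rep(c("PBP", "PNP"), each = n / 2),
                     levels = SEED_CLASSES)
  df$area <- ifelse(df$label == "PBP", -4, 4)
  kept <- select_rfecv(df, cv_folds = 3L, rng_seed = 2L)
  expect_true("area" %in% kept)
  expect_true(all(kept %in% FEATURE_NAMES[1:6]))
  # all columns identical copies of a separator: flat CV curve, minimal set
  df2 <- df
  for (cn in FEATURE_NAMES[2:6]) df2[[cn]] <- df2$area
  kept2 <- select_rfecv(df2, cv_folds = 3L, rng_seed = 2L)
  expect_equal(length(kept2), 1L)
  expect_error(select_rfecv(df[1:2, ], cv_folds = 5L), "fewer rows")
})

test_that("ANOVA selection keeps strong shifts and respects alpha", {
  ft <- sample_feature_table(40L, class_shift = 10, rng_seed = 8L)
  kept <- select_anova(ft, 0.05)
  expect_identical(sort(kept), sort(FEATURE_NAMES))  # all columns shifted
  # null columns kept at about the nominal rate
  reps <- 40L
  hits <- 0L; tests <- 0L
  for (r in seq_len(reps)) {
    null_ft <- sample_feature_table(15L, class_shift = 0,
                                    rng_seed = 6000L + r)
    hits <- hits + length(select_anova(null_ft, 0.05))
    tests <- tests + 18L
  }
  rate <- hits / tests
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.09)
  expect_error(select_anova(sample_feature_table(1L)), "2 rows")
})

test_that("contamination 0 flags nothing; bounds are validated", {
  ft <- sample_feature_table(20L, rng_seed = 9L)
  expect_true(all(flag_outliers(ft, 0)))
  expect_error(flag_outliers(ft, 0.5), "contamination")
})

test_that("planted far outliers are recovered by the isolation forest", {
  set.seed(10)
  n_in <- 1000L; n_out <- 50L
  x <- matrix(stats::rnorm(n_in * 18), n_in, 18)
  out <- matrix(stats::rnorm(n_out * 18, 0, 1) +
                  sample(c(-12, 12), n_out * 18, TRUE), n_out, 18)
  df <- as.data.frame(rbind(x, out))
  colnames(df) <- FEATURE_NAMES
  keep <- flag_outliers(df, contamination = 0.05, rng_seed = 1L,
                        by_class = FALSE)
  flagged_planted <- sum(!keep[(n_in + 1L):(n_in + n_out)])
  expect_gte(flagged_planted, 45L)
})

test_that("flagged fraction tracks the contamination rate per batch", {
  ft <- sample_feature_table(250L, rng_seed = 11L)  # 1000 rows, 4 batches
  keep <- flag_outliers(ft, 0.05, rng_seed = 2L)
  frac <- mean(!keep)
  expect_lte(abs(frac - 0.05), 2 / nrow(ft) + 1e-9)
  # cleaning preserves the column set
  expect_identical(colnames(ft[keep, ]), colnames(ft))
})
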