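# End-to-end orchestration: simulate (or read) scenes, segment, extract
# features, clean, scale, select, train and evaluate, writing every
# intermediate artifact to a run directory.

#' Pipeline configuration
#'
#' All defaults follow the production settings: contamination 0.05, GLCM
#' d = 5 at 0 degrees with 32 levels, test fraction 0.2, chi-squared k = 5,
#' variance threshold 0.02, ANOVA alpha 0.05, 5-fold CV.
#'
#' @param polarity Segmentation polarity: `"auto"`, `"bright"` or `"dark"`.
#' @param min_area_px,connectivity,pad_px Segmentation options.
#' @param features A [feature_config()].
#' @param contamination Outlier-cleaning contamination rate.
#' @param selection One of `"all"`, `"variance"`, `"chi2"`, `"sgd"`,
#'   `"rfecv"`, `"anova"` (`"all"` keeps every column).
#' @param chi2_k,variance_threshold,anova_alpha Selector parameters.
#' @param models Character vector of models to train.
#' @param test_fraction,cv_folds Split and CV settings.
#' @param rng_seed Global integer seed; all stage seeds derive from it.
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(polarity = "auto", min_area_px = 25L,
                            connectivity = 8L, pad_px = 8L,
                            features = feature_config(),
                            contamination = 0.05,
                            selection = "all", chi2_k = 5L,
                            variance_threshold = 0.02, anova_alpha = 0.05,
                            models = c("kn", "sgd", "svm", "rf"),
                            test_fraction = 0.2, cv_folds = 5L,
                            rng_seed = 42L) {
  selection <- match.arg(selection,
                         c("all", "variance", "chi2", "sgd", "rfecv",
                           "anova"))
  structure(list(polarity = polarity, min_area_px = as.integer(min_area_px),
                 connectivity = as.integer(connectivity),
                 pad_px = as.integer(pad_px), features = features,
                 contamination = contamination, selection = selection,
                 chi2_k = as.integer(chi2_k),
                 variance_threshold = variance_threshold,
                 anova_alpha = anova_alpha, models = tolower(models),
                 test_fraction = test_fraction,
                 cv_folds = as.integer(cv_folds),
                 rng_seed = as.integer(rng_seed)),
            class = "pipeline_config")
}

#' Simulate per-class scene images to disk
#'
#' Writes one PGM per scene (each scene holds seeds of a single class, as
#' acquired batches do) plus a JSON ground-truth sidecar with the seed
#' count, boxes and labels.
#'
#' @param out_dir Output directory (created if missing).
#' @param per_class Seeds per class in total.
#' @param seeds_per_scene Seeds placed in each scene image.
#' @param rng_seed Integer seed.
#' @param specs Class specifications, see [default_class_specs()].
#' @param image_shape,background_level,noise_sigma Passed to
#'   [render_scene()].
#' @return Invisibly, a data.frame manifest (scene path, class, count).
#' @export
simulate_scenes <- function(out_dir, per_class = 50L, seeds_per_scene = 50L,
                            rng_seed = 42L, specs = default_class_specs(),
                            image_shape = NULL,
                            background_level = 0.08, noise_sigma = 0.02) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  scene_no <- 0L
  for (lbl in names(specs)) {
    left <- as.integer(per_class)
    while (left > 0L) {
      scene_no <- scene_no + 1L
      n <- min(left, as.integer(seeds_per_scene))
      shape <- if (is.null(image_shape)) scene_shape_for(n) else image_shape
      sc <- render_scene(specs, stats::setNames(n, lbl), shape,
                         background_level, noise_sigma,
                         rng_seed = derive_seed(rng_seed, scene_no))
      stem <- sprintf("scene_%03d_%s", scene_no, lbl)
      write_pgm(sc$image, file.path(out_dir, paste0(stem, ".pgm")))
      jsonlite::write_json(
        list(seed_count = sc$truth$seed_count,
             boxes = sc$truth$boxes, labels = sc$truth$labels,
             seed_value = sc$truth$seed_value),
        file.path(out_dir, paste0(stem, ".json")),
        auto_unbox = TRUE, digits = NA)
      manifest[[scene_no]] <- data.frame(path = paste0(stem, ".pgm"),
                                         label = lbl, count = n)
      left <- left - n
    }
  }
  invisible(do.call(rbind, manifest))
}

# in-memory scene -> labeled feature table for one class batch
scene_features <- function(scene, label, config) {
  seg <- segment_scene(scene$image, polarity = config$polarity,
                       min_area_px = config$min_area_px,
                       connectivity = config$connectivity,
                       pad_px = config$pad_px)
  if (!length(seg$crops)) return(NULL)
  extract_feature_table(seg$crops, labels = rep(label, length(seg$crops)),
                        config = config$features)
}

#' Build the default synthetic benchmark feature table
#'
#' Renders per-class scenes totalling `per_class` seeds per class with the
#' default class specifications, runs segmentation and the 18-attribute
#' extractor on every detected seed, and returns the labeled feature table.
#' This is the imaging half of the synthetic benchmark; feed the result to
#' [run_tabular_models()] for the tabular and modelling half.
#'
#' @param per_class Seeds per class (default 500, the benchmark size).
#' @param seeds_per_scene Seeds per rendered scene image.
#' @param rng_seed Integer seed (default 42).
#' @param config A [pipeline_config()].
#' @return Labeled feature `data.frame`.
#' @export
synthetic_benchmark_features <- function(per_class = 500L,
                                         seeds_per_scene = 50L,
                                         rng_seed = 42L,
                                         config = pipeline_config()) {
  specs <- default_class_specs()
  tables <- list()
  scene_no <- 0L
  for (lbl in names(specs)) {
    left <- as.integer(per_class)
    while (left > 0L) {
      scene_no <- scene_no + 1L
      n <- min(left, as.integer(seeds_per_scene))
      sc <- render_scene(specs, stats::setNames(n, lbl),
                         scene_shape_for(n),
                         rng_seed = derive_seed(rng_seed, scene_no))
      tables[[scene_no]] <- scene_features(sc, lbl, config)
      left <- left - n
    }
  }
  do.call(rbind, tables)
}

#' Clean, scale, select and model a labeled feature table
#'
#' The tabular and modelling half of the pipeline: isolation-forest
#' cleaning per class batch, train/test split, robust scaling fitted on the
#' training rows, feature selection on the scaled training rows, then grid
#' search + fit + evaluation for each requested model.
#'
#' @param features Labeled feature `data.frame`.
#' @param config A [pipeline_config()].
#' @param learning_curves Also compute learning curves (slower).
#' @return List with `kept_rows`, `selected_columns`, `split` sizes,
#'   `reports` (named list of `"eval_report"`s with `$params` and
#'   `$cv_accuracy` attached), and optionally `curves`.
#' @export
run_tabular_models <- function(features, config = pipeline_config(),
                               learning_curves = FALSE) {
  keep <- flag_outliers(features, config$contamination,
                        rng_seed = derive_seed(config$rng_seed, 1L))
  clean <- features[keep, , drop = FALSE]
  parts <- split_train_test(clean, config$test_fraction, stratified = TRUE,
                            rng_seed = derive_seed(config$rng_seed, 2L))
  scaler <- fit_robust_scaler(parts$train)
  train <- apply_robust_scaler(parts$train, scaler)
  test <- apply_robust_scaler(parts$test, scaler)
  sel <- switch(config$selection,
    all = feature_columns(train),
    variance = select_variance(train, config$variance_threshold),
    chi2 = select_chi2(train, config$chi2_k),
    sgd = select_model_importance(train,
                                  rng_seed = derive_seed(config$rng_seed, 3L)),
    rfecv = select_rfecv(train, config$cv_folds,
                         rng_seed = derive_seed(config$rng_seed, 3L)),
    anova = select_anova(train, config$anova_alpha))
  train_s <- train[, c(sel, "label"), drop = FALSE]
  test_s <- test[, c(sel, "label"), drop = FALSE]
  reports <- list()
  curves <- list()
  for (m in config$models) {
    gs <- grid_search(m, train_s, config$cv_folds,
                      rng_seed = derive_seed(config$rng_seed, 10L))
    pred <- train_predict(m, gs$params, train_s, test_s,
                          rng_seed = derive_seed(config$rng_seed, 11L))
    rep <- evaluate(test_s$label, pred, model = MODEL_NAMES[[m]])
    rep$params <- gs$params
    rep$cv_accuracy <- gs$cv_accuracy
    reports[[m]] <- rep
    if (learning_curves) {
      n_tr <- nrow(train_s)
      sizes <- unique(pmax(20L, round(seq(0.1, 1, length.out = 5) *
                                        floor(n_tr * (config$cv_folds - 1) /
                                                config$cv_folds))))
      curves[[m]] <- learning_curve(m, gs$params, train_s, sizes,
                                    config$cv_folds,
                                    rng_seed = derive_seed(config$rng_seed,
                                                           12L))
    }
  }
  out <- list(kept_rows = keep, n_clean = nrow(clean),
              selected_columns = sel,
              split = c(train = nrow(parts$train), test = nrow(parts$test)),
              scaler = scaler, reports = reports)
  if (learning_curves) out$curves <- curves
  out
}

#' Run the full pipeline into a run directory
#'
#' Either reads PGM scenes (with `<stem>.json` ground-truth/label sidecars
#' or a class label embedded as `_PBP` etc. in the filename) from `in_dir`,
#' or simulates them when `simulate = TRUE`. Writes crops (16-bit PNG),
#' `features.csv`, `clean.csv`, `selected.csv`, `report.json` and a
#' `log.txt` with stage counts.
#'
#' @param out_dir Run directory (created).
#' @param in_dir Directory of input scenes (ignored when simulating).
#' @param simulate Generate synthetic scenes instead of reading inputs.
#' @param per_class Seeds per class when simulating.
#' @param config A [pipeline_config()].
#' @param write_crops Write per-seed PNG crops (default `TRUE`).
#' @return Invisibly, the [run_tabular_models()] result.
#' @export
run_pipeline <- function(out_dir, in_dir = NULL, simulate = is.null(in_dir),
                         per_class = 50L, config = pipeline_config(),
                         write_crops = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "log.txt")
  logf <- function(...) {
    msg <- sprintf(...)
    cat(msg, "\n", file = log_path, append = TRUE, sep = "")
    message(msg)
  }
  crops_dir <- file.path(out_dir, "crops")
  if (write_crops) dir.create(crops_dir, showWarnings = FALSE)

  scenes <- list()
  if (simulate) {
    scene_no <- 0L
    for (lbl in SEED_CLASSES) {
      left <- as.integer(per_class)
      while (left > 0L) {
        scene_no <- scene_no + 1L
        n <- min(left, 50L)
        sc <- render_scene(default_class_specs(), stats::setNames(n, lbl),
                           scene_shape_for(n),
                           rng_seed = derive_seed(config$rng_seed,
                                                  scene_no))
        scenes[[scene_no]] <- list(image = sc$image, label = lbl,
                                   name = sprintf("scene_%03d_%s",
                                                  scene_no, lbl))
        left <- left - n
      }
    }
    logf("simulated %d scenes (%d seeds per class)", length(scenes),
         per_class)
  } else {
    paths <- list.files(in_dir, pattern = "\\.pgm$", full.names = TRUE)
    if (!length(paths)) stop("stage input: no PGM scenes in ", in_dir)
    for (p in paths) {
      stem <- sub("\\.pgm$", "", basename(p))
      side <- file.path(in_dir, paste0(stem, ".json"))
      lbl <- if (file.exists(side)) {
        gt <- jsonlite::read_json(side, simplifyVector = TRUE)
        unique(gt$labels)[1L]
      } else {
        hit <- regmatches(stem, regexpr("PBP|PBA|PNP|PNA", stem))
        if (length(hit)) hit else NA_character_
      }
      scenes[[length(scenes) + 1L]] <- list(image = read_pgm(p), label = lbl,
                                            name = stem)
    }
    logf("read %d scenes from %s", length(scenes), in_dir)
  }

  tables <- list()
  for (si in seq_along(scenes)) {
    sc <- scenes[[si]]
    seg <- tryCatch(
      segment_scene(sc$image, polarity = config$polarity,
                    min_area_px = config$min_area_px,
                    connectivity = config$connectivity,
                    pad_px = config$pad_px),
      error = function(e) stop("stage segmentation failed on ", sc$name,
                               ": ", conditionMessage(e)))
    logf("%s: threshold %.0f, %d seeds", sc$name, seg$threshold,
         length(seg$crops))
    if (write_crops) {
      for (ci in seq_along(seg$crops))
        write_crop_png(seg$crops[[ci]]$pixels,
                       file.path(crops_dir,
                                 sprintf("%s_seed%03d.png", sc$name, ci)))
    }
    if (length(seg$crops))
      tables[[length(tables) + 1L]] <-
        extract_feature_table(seg$crops,
                              labels = rep(sc$label, length(seg$crops)),
                              config = config$features)
  }
  features <- do.call(rbind, tables)
  utils::write.csv(features, file.path(out_dir, "features.csv"),
                   row.names = FALSE)
  logf("features: %d rows x %d columns", nrow(features),
       ncol(features) - 1L)

  res <- run_tabular_models(features, config)
  clean <- features[res$kept_rows, , drop = FALSE]
  utils::write.csv(clean, file.path(out_dir, "clean.csv"),
                   row.names = FALSE)
  logf("clean: %d rows kept, %d dropped", nrow(clean),
       nrow(features) - nrow(clean))
  utils::write.csv(clean[, c(res$selected_columns, "label")],
                   file.path(out_dir, "selected.csv"), row.names = FALSE)
  logf("selected %d columns: %s", length(res$selected_columns),
       paste(res$selected_columns, collapse = ", "))

  report <- lapply(res$reports, function(r) {
    list(model = r$model, accuracy = r$accuracy,
         macro_precision = r$macro_precision,
         macro_recall = r$macro_recall, macro_f1 = r$macro_f1,
         confusion = r$confusion, params = r$params,
         cv_accuracy = r$cv_accuracy)
  })
  jsonlite::write_json(list(split = as.list(res$split), models = report),
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  for (m in names(res$reports))
    logf("%s: accuracy %.3f (cv %.3f)", res$reports[[m]]$model,
         res$reports[[m]]$accuracy, res$reports[[m]]$cv_accuracy)
  invisible(res)
}
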