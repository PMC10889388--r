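# Synthetic CFA seed scenes.
#
# Seeds are rendered as elliptical blobs whose interior intensity is the
# class mean modulated by an oriented sinusoidal texture plus Gaussian grain;
# the whole frame is multiplied by a 2x2-periodic Bayer gain pattern (RGGB)
# emulating per-photosite spectral sensitivity, then quantized to 16 bits.
# The four default classes mimic white/black pepper crossed with a
# Penja-like/other-like texture-and-shape contrast: the white/black split is
# easy (intensity), the within-colour split hard (texture frequency and
# ellipse eccentricity only).

BAYER_GAINS <- matrix(c(0.8, 1.0, 1.0, 0.7), 2L, 2L, byrow = TRUE)  # RGGB

#' Specification of one synthetic seed class
#'
#' @param label Class label, one of `PBP`, `PBA`, `PNP`, `PNA`.
#' @param mean_intensity Mean interior intensity as a fraction of full scale.
#' @param texture_frequency Spatial frequency (cycles/pixel, horizontal) of
#'   the intra-seed sinusoidal texture.
#' @param texture_amplitude Amplitude of the texture, fraction of full scale;
#'   `mean_intensity +/- texture_amplitude` must stay in `[0, 1]`.
#' @param axis_ratio_range Length-2 range for the minor/major ellipse axis
#'   ratio.
#' @param radius_range_px Length-2 range for the major semi-axis in pixels
#'   (minimum 4 so every seed survives segmentation).
#' @return An object of class `"seed_class_spec"`.
#' @export
seed_class_spec <- function(label, mean_intensity, texture_frequency,
                            texture_amplitude, axis_ratio_range,
                            radius_range_px) {
  label <- match.arg(label, SEED_CLASSES)
  stopifnot(length(axis_ratio_range) == 2L, length(radius_range_px) == 2L)
  if (mean_intensity + texture_amplitude > 1 ||
      mean_intensity - texture_amplitude < 0)
    stop("mean_intensity +/- texture_amplitude must stay within [0, 1]")
  if (radius_range_px[1L] < 4)
    stop("radius_range_px minimum must be >= 4")
  if (axis_ratio_range[1L] <= 0 || axis_ratio_range[2L] > 1)
    stop("axis_ratio_range must lie in (0, 1]")
  structure(list(label = label, mean_intensity = mean_intensity,
                 texture_frequency = texture_frequency,
                 texture_amplitude = texture_amplitude,
                 axis_ratio_range = as.numeric(axis_ratio_range),
                 radius_range_px = as.numeric(radius_range_px)),
            class = "seed_class_spec")
}

#' Default class specifications for the four seed types
#'
#' White classes sit at mean intensity 0.75, black at 0.25; Penja-like and
#' other-like classes differ only in texture frequency (0.20 vs 0.12
#' cycles/px) and ellipse axis ratio, so colour separation is easy while
#' within-colour separation rests on texture and shape.
#'
#' @return Named list of four [seed_class_spec()] objects in class order.
#' @export
default_class_specs <- function() {
  list(
    PBP = seed_class_spec("PBP", 0.75, 0.20, 0.10, c(0.55, 0.70), c(10, 16)),
    PBA = seed_class_spec("PBA", 0.75, 0.12, 0.10, c(0.75, 0.90), c(10, 16)),
    PNP = seed_class_spec("PNP", 0.25, 0.20, 0.06, c(0.55, 0.70), c(10, 16)),
    PNA = seed_class_spec("PNA", 0.25, 0.12, 0.06, c(0.75, 0.90), c(10, 16))
  )
}

#' Frame size holding the benchmark areal seed density
#'
#' Scenes are rendered at a roughly constant seed density (about 50 seeds
#' per 1024 x 1024 frame, emulating a fixed camera over a standard pinch of
#' seeds). Constant density keeps the foreground mass of the intensity
#' histogram stable, which global Otsu thresholding relies on for the
#' low-contrast dark classes.
#'
#' @param n Seeds in the scene.
#' @return `c(rows, cols)` for [render_scene()].
#' @export
scene_shape_for <- function(n) {
  side <- max(180L, as.integer(ceiling(sqrt(n / 50) * 1024)))
  c(side, side)
}

#' Render a synthetic CFA seed scene
#'
#' Places the requested number of seeds per class at non-overlapping random
#' positions (with a margin), renders each as a textured ellipse, applies the
#' RGGB Bayer gain raster and quantizes to 16 bits.
#'
#' @param specs Named list of [seed_class_spec()] (defaults to
#'   [default_class_specs()]).
#' @param counts Named integer vector, seeds to place per class label.
#' @param image_shape `c(rows, cols)` of the frame.
#' @param background_level Background intensity, fraction of full scale.
#' @param noise_sigma Standard deviation of the intra-seed Gaussian grain,
#'   fraction of full scale.
#' @param rng_seed Integer seed; identical seeds give bit-identical scenes.
#' @param max_retries Placement retries per seed before failing.
#' @return A list with `image` (a [cfa_image()]) and `truth`, a list with
#'   `seed_count`, `boxes` (matrix of inclusive `row_min, col_min, row_max,
#'   col_max` rows), `labels` and `seed_value`.
#' @export
render_scene <- function(specs = default_class_specs(),
                         counts = c(PBP = 10L),
                         image_shape = c(1024L, 1024L),
                         background_level = 0.08,
                         noise_sigma = 0.02,
                         rng_seed = 1L,
                         max_retries = 200L) {
  stopifnot(background_level >= 0, background_level <= 1, noise_sigma >= 0)
  counts <- counts[counts > 0]
  labels_wanted <- rep(names(counts), times = as.integer(counts))
  h <- as.integer(image_shape[1L]); w <- as.integer(image_shape[2L])
  canvas <- matrix(background_level, h, w)
  n_seed <- length(labels_wanted)
  boxes <- matrix(integer(0), 0L, 4L,
                  dimnames = list(NULL, c("row_min", "col_min",
                                          "row_max", "col_max")))
  placed_labels <- character(0)

  if (n_seed > 0L) {
    for (lbl in unique(labels_wanted)) {
      if (is.null(specs[[lbl]])) stop("no class spec for label ", lbl)
    }
    margin <- 12L  # keeps crops (with padding) inside the frame
    occ <- matrix(FALSE, h, w)  # occupied pixels incl. spacing halo
    for (k in seq_len(n_seed)) {
      lbl <- labels_wanted[k]
      sp <- specs[[lbl]]
      placed <- with_seed(derive_seed(rng_seed, k), {
        ok <- FALSE
        for (try in seq_len(max_retries)) {
          a <- stats::runif(1, sp$radius_range_px[1L], sp$radius_range_px[2L])
          ratio <- stats::runif(1, sp$axis_ratio_range[1L],
                                sp$axis_ratio_range[2L])
          b <- a * ratio
          phi <- stats::runif(1, 0, pi)       # ellipse orientation
          phase <- stats::runif(1, 0, 2 * pi) # texture phase
          r_ext <- ceiling(a) + 1L
          cr <- floor(stats::runif(1, margin + r_ext + 1,
                                   h - margin - r_ext))
          cc <- floor(stats::runif(1, margin + r_ext + 1,
                                   w - margin - r_ext))
          rows <- (cr - r_ext):(cr + r_ext)
          cols <- (cc - r_ext):(cc + r_ext)
          halo <- 6L
          hrows <- max(1L, cr - r_ext - halo):min(h, cr + r_ext + halo)
          hcols <- max(1L, cc - r_ext - halo):min(w, cc + r_ext + halo)
          if (any(occ[hrows, hcols])) next
          # ellipse interior in rotated frame
          dy <- outer(rows - cr, rep(1, length(cols)))
          dx <- outer(rep(1, length(rows)), cols - cc)
          u <- dx * cos(phi) + dy * sin(phi)
          v <- -dx * sin(phi) + dy * cos(phi)
          inside <- (u / a)^2 + (v / b)^2 <= 1
          if (!any(inside)) next
          colpos <- outer(rep(1, length(rows)), cols)
          tex <- sp$mean_intensity +
            sp$texture_amplitude * sin(2 * pi * sp$texture_frequency * colpos +
                                       phase) +
            stats::rnorm(length(dx), 0, noise_sigma)
          patch <- canvas[rows, cols]
          patch[inside] <- pmin(1, pmax(0, tex[inside]))
          canvas[rows, cols] <- patch
          occ[hrows, hcols] <- TRUE
          rr <- range(rows[row(inside)[inside]])
          cc2 <- range(cols[col(inside)[inside]])
          boxes <- rbind(boxes, c(rr[1L], cc2[1L], rr[2L], cc2[2L]))
          placed_labels <- c(placed_labels, lbl)
          ok <- TRUE
          break
        }
        ok
      })
      if (!placed)
        stop("could not place a seed of class ", lbl,
             " after ", max_retries, " retries")
    }
  }

  gains <- BAYER_GAINS[((seq_len(h) - 1L) %% 2L) + 1L,
                       ((seq_len(w) - 1L) %% 2L) + 1L, drop = FALSE]
  px <- matrix(as.integer(round(pmin(1, pmax(0, canvas * gains)) * 65535)),
               h, w)
  truth <- list(seed_count = nrow(boxes), boxes = boxes,
                labels = placed_labels, seed_value = as.integer(rng_seed))
  list(image = cfa_image(px, origin = "synthetic"), truth = truth)
}

#' Sample a synthetic 18-column feature table directly
#'
#' Bypasses the imaging stages: draws Gaussian feature rows around
#' class-specific mean profiles. Every attribute carries some class signal
#' (scaled by `class_shift`) through a fixed pattern matrix, so selection
#' stages see structure in all columns, as with real seed batches.
#'
#' @param n_per_class Rows per class; either a single integer or a named
#'   vector over the four class labels.
#' @param class_shift Effect size: multiplier on the between-class mean
#'   offsets, in units of `noise_sd`. `0` gives an exchangeable null table.
#' @param noise_sd Within-class standard deviation (must be positive).
#' @param rng_seed Integer seed.
#' @return A `data.frame` with the 18 [FEATURE_NAMES] columns and a `label`
#'   factor in class order.
#' @export
sample_feature_table <- function(n_per_class = 100L, class_shift = 2,
                                 noise_sd = 1, rng_seed = 1L) {
  if (length(n_per_class) == 1L)
    n_per_class <- stats::setNames(rep(as.integer(n_per_class), 4L),
                                   SEED_CLASSES)
  n_per_class <- n_per_class[SEED_CLASSES]
  if (anyNA(n_per_class) || any(n_per_class < 1L))
    stop("n_per_class must be >= 1 for every class")
  if (noise_sd <= 0) stop("noise_sd must be positive")
  p <- length(FEATURE_NAMES)
  # fixed class offset patterns (rows: classes), magnitudes in [0.3, 1];
  # deterministic, chosen once so every column carries signal
  pat <- with_seed(20240131L, matrix(stats::runif(4L * p, 0.3, 1) *
                                       sample(c(-1, 1), 4L * p, TRUE),
                                     4L, p))
  base <- seq(2, 4, length.out = p)  # arbitrary baseline profile
  rows <- with_seed(rng_seed, {
    out <- vector("list", 4L)
    for (ci in seq_len(4L)) {
      n <- n_per_class[ci]
      mu <- base + class_shift * noise_sd * pat[ci, ]
      out[[ci]] <- matrix(stats::rnorm(n * p, 0, noise_sd), n, p,
                          byrow = FALSE) +
        matrix(mu, n, p, byrow = TRUE)
    }
    out
  })
  x <- do.call(rbind, rows)
  colnames(x) <- FEATURE_NAMES
  df <- as.data.frame(x)
  df$label <- factor(rep(SEED_CLASSES, times = n_per_class),
                     levels = SEED_CLASSES)
  df
}
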