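# Per-seed feature extraction: 6 shape attributes, 2 Gabor filter
# statistics, 5 LBP texture statistics and 5 GLCM texture statistics.

#' Feature extraction configuration
#'
#' Bundles the tunable parameters of the 18-attribute extractor. GLCM
#' defaults follow the production setting (distance 5 pixels, angle 0
#' degrees, 32 grey levels, symmetric pooling); the Gabor filter is a single
#' fixed zero-DC complex kernel at 0 degrees, 0.25 cycles/pixel, sigma 3 px.
#'
#' @param ng Grey levels for GLCM quantization.
#' @param d GLCM pixel distance.
#' @param theta GLCM angle in degrees (0, 45, 90, 135).
#' @param symmetric Symmetric GLCM pooling.
#' @param gabor_frequency Gabor tuning frequency, cycles/pixel.
#' @param gabor_sigma Gabor Gaussian envelope sigma, pixels.
#' @param gabor_theta Gabor orientation, degrees.
#' @return List of class `"feature_config"`.
#' @export
feature_config <- function(ng = 32L, d = 5L, theta = 0, symmetric = TRUE,
                           gabor_frequency = 0.25, gabor_sigma = 3,
                           gabor_theta = 0) {
  structure(list(ng = as.integer(ng), d = as.integer(d), theta = theta,
                 symmetric = symmetric, gabor_frequency = gabor_frequency,
                 gabor_sigma = gabor_sigma, gabor_theta = gabor_theta),
            class = "feature_config")
}

# Moore-neighbour boundary tracing. Returns the perimeter of the traced
# 8-connected outer boundary chain. Step weights use the classical
# Vossepoel-Smeulders correction (0.948 per axial step, 1.340 per diagonal
# step) so the estimate converges to the true contour length of smooth
# shapes - the naive 1/sqrt(2) chain overestimates a circle's perimeter by
# ~5%, which would bias compactness well below 1. Degenerate regions whose
# chain has no steps (single pixel) use the unit-square perimeter 4.
PERIM_W_AXIAL <- 0.948
PERIM_W_DIAG <- 1.340

trace_perimeter <- function(mask) {
  fg <- mask != 0L
  h <- nrow(fg); w <- ncol(fg)
  area <- sum(fg)
  if (area == 0L) stop("empty region")
  if (area == 1L) return(4)  # isolated pixel as a unit square
  m <- matrix(FALSE, h + 2L, w + 2L)  # pad to avoid bound checks
  m[2:(h + 1L), 2:(w + 1L)] <- fg
  # start: first foreground pixel in raster order; we arrived from its west
  idx <- which(t(m))  # row-major scan
  first <- idx[1L]
  start <- c((first - 1L) %/% (w + 2L) + 1L, (first - 1L) %% (w + 2L) + 1L)
  # clockwise Moore neighbourhood order, indexed 1..8 starting at west
  dirs <- matrix(c(0L, -1L,  -1L, -1L,  -1L, 0L,  -1L, 1L,
                   0L, 1L,   1L, 1L,    1L, 0L,   1L, -1L),
                 ncol = 2L, byrow = TRUE)
  step_w <- ifelse(dirs[, 1L] != 0L & dirs[, 2L] != 0L,
                   PERIM_W_DIAG, PERIM_W_AXIAL)
  dir_index <- function(from, to) {
    d <- to - from
    which(dirs[, 1L] == d[1L] & dirs[, 2L] == d[2L])
  }
  cur <- start
  back <- start + dirs[1L, ]  # background pixel west of the start
  perim <- 0
  start_back <- back
  max_steps <- 4L * (area + 4L) * 2L
  steps <- 0L
  repeat {
    k0 <- dir_index(cur, back)
    found <- FALSE
    for (t in seq_len(8L)) {
      k <- (k0 + t - 1L) %% 8L + 1L
      nb <- cur + dirs[k, ]
      if (m[nb[1L], nb[2L]]) {
        back <- cur + dirs[(k - 2L) %% 8L + 1L, ]  # last background examined
        perim <- perim + step_w[k]
        cur <- nb
        found <- TRUE
        break
      }
    }
    if (!found) return(4)  # isolated after all (should not happen, area > 1)
    steps <- steps + 1L
    # Jacob's stopping criterion: back at the start, entered the same way
    if (all(cur == start) && all(back == start_back)) break
    if (steps > max_steps) break
  }
  max(perim, 4)
}

#' Shape attributes of a segmented seed
#'
#' @param mask 0/1 matrix marking the region's foreground inside its crop.
#' @return Named vector: `area` (pixel count), `perimeter` (8-connected
#'   boundary chain length, diagonals weighted sqrt(2)), `compactness`
#'   (`4*pi*area / perimeter^2`, 1 for a disk), `extent` (area over
#'   bounding-box area), `width`, `height` (bounding-box extents).
#' @export
shape_features <- function(mask) {
  fg <- mask != 0L
  area <- sum(fg)
  if (area == 0L) stop("empty region")
  rows <- range(which(rowSums(fg) > 0L))
  cols <- range(which(colSums(fg) > 0L))
  height <- rows[2L] - rows[1L] + 1L
  width <- cols[2L] - cols[1L] + 1L
  perim <- trace_perimeter(fg)
  c(area = as.numeric(area),
    perimeter = perim,
    compactness = 4 * pi * area / perim^2,
    extent = area / (width * height),
    width = as.numeric(width),
    height = as.numeric(height))
}

# complex Gabor kernel, zero-DC (sum of coefficients is exactly 0 so the
# response to a constant image vanishes)
gabor_kernel <- function(frequency = 0.25, sigma = 3, theta = 0) {
  half <- ceiling(3 * sigma)
  idx <- (-half):half
  yy <- outer(idx, rep(1, length(idx)))
  xx <- outer(rep(1, length(idx)), idx)
  th <- theta * pi / 180
  u <- xx * cos(th) + yy * sin(th)
  g <- exp(-(xx^2 + yy^2) / (2 * sigma^2)) *
    exp(2i * pi * frequency * u)
  g - sum(g) / length(g)
}

# valid-mode 2-D convolution (correlation) of a real image with a complex
# kernel, via FFT
conv2_valid <- function(img, ker) {
  hi <- nrow(img); wi <- ncol(img)
  hk <- nrow(ker); wk <- ncol(ker)
  if (hi < hk || wi < wk) stop("crop smaller than the Gabor kernel")
  hp <- hi + hk - 1L; wp <- wi + wk - 1L
  a <- matrix(0 + 0i, hp, wp); a[1:hi, 1:wi] <- img
  b <- matrix(0 + 0i, hp, wp); b[1:hk, 1:wk] <- ker[hk:1, wk:1]  # correlation
  full <- stats::fft(stats::fft(a) * stats::fft(b), inverse = TRUE) / (hp * wp)
  full[hk:hi, wk:wi, drop = FALSE]
}

#' Gabor filter statistics of a crop
#'
#' Convolves the crop (on the [0,1] scale) with a fixed zero-DC complex
#' Gabor kernel and returns the mean and standard deviation of the response
#' magnitude over the valid region. Intensity-shift invariant.
#'
#' @param pixels Integer matrix on the 16-bit scale.
#' @param frequency,sigma,theta Kernel parameters, see [feature_config()].
#' @return Named vector `c(gabor_mean, gabor_std)`.
#' @export
gabor_features <- function(pixels, frequency = 0.25, sigma = 3, theta = 0) {
  ker <- gabor_kernel(frequency, sigma, theta)
  resp <- conv2_valid(pixels / 65535, ker)
  mag <- Mod(resp)
  c(gabor_mean = mean(mag),
    gabor_std = stats::sd(as.vector(mag)))
}

#' Local binary pattern code image
#'
#' 8-neighbour, radius-1, rotation-variant codes: bit k is set when the k-th
#' neighbour (counter-clockwise from east) is `>=` the centre pixel.
#' Computed for interior pixels only.
#'
#' @param pixels Numeric/integer matrix.
#' @return Integer matrix of codes in `0..255`, dimensions
#'   `(nrow-2) x (ncol-2)`.
#' @export
lbp_codes <- function(pixels) {
  h <- nrow(pixels); w <- ncol(pixels)
  if (h < 3L || w < 3L) stop("crop must be at least 3x3")
  ctr <- pixels[2:(h - 1L), 2:(w - 1L)]
  # neighbour offsets counter-clockwise from east (dr, dc); row axis points
  # down so "north" is dr = -1
  offs <- matrix(c(0L, 1L, -1L, 1L, -1L, 0L, -1L, -1L,
                   0L, -1L, 1L, -1L, 1L, 0L, 1L, 1L),
                 ncol = 2L, byrow = TRUE)
  code <- matrix(0L, h - 2L, w - 2L)
  for (k in seq_len(8L)) {
    nb <- pixels[(2:(h - 1L)) + offs[k, 1L], (2:(w - 1L)) + offs[k, 2L]]
    code <- code + bitwShiftL(as.integer(nb >= ctr), k - 1L)
  }
  code
}

#' LBP texture statistics of a crop
#'
#' Computes the LBP code image (P=8, R=1), a symmetric GLCM of the codes at
#' distance 1, angle 0 (256 levels), and five texture statistics of that
#' GLCM: contrast, correlation, energy, homogeneity, entropy. Invariant to
#' monotone intensity rescaling (LBP codes only compare ranks).
#'
#' @param pixels Integer matrix (at least 4x4 so the code image admits a
#'   distance-1 pair).
#' @return Named vector of the five `lbp_*` statistics.
#' @export
lbp_features <- function(pixels) {
  codes <- lbp_codes(pixels)
  g <- compute_glcm(codes, ng = 256L, d = 1L, theta = 0, symmetric = TRUE)
  d <- texture_descriptors(g, c("contrast", "correlation", "energy",
                                "homogeneity", "entropy"))
  stats::setNames(d[c("contrast", "correlation", "energy", "homogeneity",
                      "entropy")],
                  c("lbp_contrast", "lbp_correlation", "lbp_energy",
                    "lbp_homogeneity", "lbp_entropy"))
}

#' Extract the 18-attribute feature vector of a seed crop
#'
#' Assembles shape (from the region mask), Gabor, LBP and GLCM attribute
#' groups. The GLCM block is computed on the quantized crop restricted to
#' the seed mask at the configured offset (default d=5, theta=0).
#'
#' @param crop A crop from [extract_crops()] (list with `pixels` and
#'   `mask`), or an integer pixel matrix if `mask` is given separately.
#' @param mask Optional 0/1 matrix overriding `crop$mask`.
#' @param config A [feature_config()].
#' @return Named numeric vector with the 18 [FEATURE_NAMES] entries, in
#'   fixed order.
#' @export
extract_features <- function(crop, mask = NULL, config = feature_config()) {
  if (is.list(crop)) {
    px <- crop$pixels
    if (is.null(mask)) mask <- crop$mask
  } else {
    px <- crop
  }
  if (is.null(mask)) stop("a region mask is required")
  shp <- shape_features(mask)
  gab <- gabor_features(px, config$gabor_frequency, config$gabor_sigma,
                        config$gabor_theta)
  lbp <- lbp_features(px)
  q <- quantize_grey(px, config$ng)
  # the masked GLCM can be pair-less for very narrow seeds at d = 5; fall
  # back to the unmasked crop so such a seed still gets texture attributes
  g <- tryCatch(
    compute_glcm(q, ng = config$ng, d = config$d, theta = config$theta,
                 symmetric = config$symmetric, mask = mask),
    error = function(e)
      compute_glcm(q, ng = config$ng, d = config$d, theta = config$theta,
                   symmetric = config$symmetric))
  td <- texture_descriptors(g, c("dissimilarity", "correlation", "contrast",
                                 "homogeneity", "energy"))
  glcm_block <- c(glcm_dissimilarity = unname(td["dissimilarity"]),
                  glcm_correlation = unname(td["correlation"]),
                  glcm_contrast = unname(td["contrast"]),
                  glcm_homogeneity = unname(td["homogeneity"]),
                  glcm_asm = unname(td["energy"]))
  out <- c(shp, gab, lbp, glcm_block)
  stopifnot(identical(names(out), FEATURE_NAMES))
  out
}

#' Extract a labeled feature table from a list of crops
#'
#' @param crops List of crops (see [extract_crops()]).
#' @param labels Optional per-crop class labels.
#' @param config A [feature_config()].
#' @return `data.frame` with the 18 feature columns and, when labels are
#'   given, a `label` factor column in class order.
#' @export
extract_feature_table <- function(crops, labels = NULL,
                                  config = feature_config()) {
  rows <- t(vapply(crops, extract_features, numeric(18L), config = config))
  df <- as.data.frame(rows)
  colnames(df) <- FEATURE_NAMES
  if (!is.null(labels)) {
    stopifnot(length(labels) == length(crops))
    df$label <- factor(as.character(labels), levels = SEED_CLASSES)
  }
  df
}
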