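# Otsu thresholding, mask construction, 8-connected component labeling and
# bounding-box cropping. The threshold is computed on a 256-bin histogram of
# the 16-bit range: sparse 65536-bin histograms give unstable between-class
# variance estimates, and the grey-level compression mirrors the quantization
# used for texture work.

#' Otsu threshold of a CFA image
#'
#' Builds a `histogram_bins`-bin histogram over the full 16-bit range and
#' returns the bin edge that maximizes the between-class variance of the
#' two-class split. Deterministic; ties resolve to the lowest edge.
#'
#' @param image A [cfa_image()] or integer matrix on the 16-bit scale.
#' @param histogram_bins Number of histogram bins (default 256).
#' @return Threshold intensity on the 16-bit scale: pixels `> threshold` are
#'   the upper class.
#' @export
otsu_threshold <- function(image, histogram_bins = 256L) {
  px <- if (inherits(image, "cfa_image")) image$pixels else image
  if (length(unique(as.vector(px))) < 2L)
    stop("degenerate input: image has fewer than 2 distinct values")
  nb <- as.integer(histogram_bins)
  width <- 65536 / nb
  bins <- pmin(nb - 1L, px %/% width)  # 0 .. nb-1
  counts <- tabulate(as.integer(bins) + 1L, nbins = nb)
  p <- counts / sum(counts)
  lev <- seq_len(nb) - 1L
  # cumulative class probability / mean for split after bin t (t = 0..nb-2)
  w0 <- cumsum(p)
  mu <- cumsum(p * lev)
  mu_t <- mu[nb]
  w0 <- w0[-nb]; mu0 <- mu[-nb]
  sigma_b <- (mu_t * w0 - mu0)^2 / (w0 * (1 - w0))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  t_star <- which.max(sigma_b) - 1L  # upper edge of bin t_star
  (t_star + 1L) * width - 1  # last intensity value inside the lower class
}

#' Binarize an image at a threshold
#'
#' @param image A [cfa_image()] or integer matrix.
#' @param threshold Intensity threshold.
#' @param polarity `"bright"` selects pixels strictly above the threshold
#'   (seeds brighter than background); `"dark"` selects pixels at or below it.
#' @return Integer 0/1 matrix of the same shape.
#' @export
binarize <- function(image, threshold, polarity = c("bright", "dark")) {
  polarity <- match.arg(polarity)
  px <- if (inherits(image, "cfa_image")) image$pixels else image
  m <- if (polarity == "bright") px > threshold else px <= threshold
  mode(m) <- "integer"
  m
}

#' Label connected foreground components
#'
#' Finds maximal connected foreground regions (8-neighbour by default) by
#' flood fill, discards components smaller than `min_area_px`, and returns
#' them sorted by bounding-box `(row_min, col_min)`.
#'
#' @param mask Integer/logical 0/1 matrix.
#' @param connectivity 4 or 8.
#' @param min_area_px Minimum component area in pixels kept (default 25,
#'   which removes CFA-raster speckle).
#' @return An object of class `"seed_regions"`: list with `regions` (each a
#'   list with `label_id`, `area_px`, `bbox` as inclusive `c(row_min,
#'   col_min, row_max, col_max)`, and `centroid`), `labels` (integer matrix,
#'   0 = background), `discarded_px` (foreground pixels dropped by the area
#'   filter).
#' @export
label_components <- function(mask, connectivity = 8L, min_area_px = 25L) {
  stopifnot(connectivity %in% c(4L, 8L))
  h <- nrow(mask); w <- ncol(mask)
  fg <- mask != 0L
  labels <- matrix(0L, h, w)
  # neighbour offsets in linear (column-major) index space; guard rows via
  # row coordinate checks
  comp <- list()
  next_id <- 0L
  todo <- which(fg)
  visited <- matrix(FALSE, h, w)
  dr4 <- c(-1L, 1L, 0L, 0L); dc4 <- c(0L, 0L, -1L, 1L)
  dr8 <- c(dr4, -1L, -1L, 1L, 1L); dc8 <- c(dc4, -1L, 1L, -1L, 1L)
  dr <- if (connectivity == 8L) dr8 else dr4
  dc <- if (connectivity == 8L) dc8 else dc4
  for (start in todo) {
    if (visited[start]) next
    next_id <- next_id + 1L
    frontier <- start
    visited[start] <- TRUE
    members <- start
    while (length(frontier)) {
      fr <- ((frontier - 1L) %% h) + 1L
      fc <- ((frontier - 1L) %/% h) + 1L
      nbr_r <- rep(fr, times = length(dr)) + rep(dr, each = length(fr))
      nbr_c <- rep(fc, times = length(dc)) + rep(dc, each = length(fc))
      keep <- nbr_r >= 1L & nbr_r <= h & nbr_c >= 1L & nbr_c <= w
      idx <- unique((nbr_c[keep] - 1L) * h + nbr_r[keep])
      idx <- idx[fg[idx] & !visited[idx]]
      visited[idx] <- TRUE
      members <- c(members, idx)
      frontier <- idx
    }
    labels[members] <- next_id
    comp[[next_id]] <- members
  }
  discarded <- 0L
  regions <- list()
  for (id in seq_along(comp)) {
    members <- comp[[id]]
    if (length(members) < min_area_px) {
      discarded <- discarded + length(members)
      labels[members] <- 0L
      next
    }
    r <- ((members - 1L) %% h) + 1L
    c <- ((members - 1L) %/% h) + 1L
    regions[[length(regions) + 1L]] <- list(
      label_id = id,
      area_px = length(members),
      bbox = c(row_min = min(r), col_min = min(c),
               row_max = max(r), col_max = max(c)),
      centroid = c(row = mean(r), col = mean(c))
    )
  }
  if (length(regions)) {
    ord <- order(vapply(regions, function(x) x$bbox[1L], 0),
                 vapply(regions, function(x) x$bbox[2L], 0))
    regions <- regions[ord]
  }
  structure(list(regions = regions, labels = labels,
                 discarded_px = discarded,
                 connectivity = connectivity, min_area_px = min_area_px),
            class = "seed_regions")
}

#' @export
print.seed_regions <- function(x, ...) {
  cat(sprintf("<seed_regions> %d regions (%d-connected, min area %d px)\n",
              length(x$regions), x$connectivity, x$min_area_px))
  invisible(x)
}

#' Extract padded bounding-box crops for each region
#'
#' Each crop is the region's bounding box grown by `pad_px` on every side and
#' clipped to the image bounds; the region's own foreground mask is carried
#' along for mask-aware feature computation.
#'
#' @param image A [cfa_image()] or integer matrix.
#' @param regions A `"seed_regions"` object from [label_components()].
#' @param pad_px Padding in pixels (default 8).
#' @return List of crops; each is a list with `pixels`, `mask` (0/1 matrix of
#'   this region only), `region` and `bbox_crop` (the crop's own inclusive
#'   box in scene coordinates).
#' @export
extract_crops <- function(image, regions, pad_px = 8L) {
  px <- if (inherits(image, "cfa_image")) image$pixels else image
  stopifnot(inherits(regions, "seed_regions"))
  h <- nrow(px); w <- ncol(px)
  lapply(regions$regions, function(reg) {
    b <- reg$bbox
    r0 <- max(1L, b[1L] - pad_px); c0 <- max(1L, b[2L] - pad_px)
    r1 <- min(h, b[3L] + pad_px); c1 <- min(w, b[4L] + pad_px)
    sub <- px[r0:r1, c0:c1, drop = FALSE]
    msk <- regions$labels[r0:r1, c0:c1, drop = FALSE]
    msk <- (msk == reg$label_id) * 1L
    list(pixels = sub, mask = msk, region = reg,
         bbox_crop = c(row_min = r0, col_min = c0, row_max = r1,
                       col_max = c1))
  })
}

#' Segment a scene into seed crops
#'
#' Convenience wrapper: Otsu threshold, binarize, label components, crop.
#' Polarity `"auto"` picks the orientation whose foreground covers less than
#' half the frame (seeds are sparse on a uniform background).
#'
#' @param image A [cfa_image()].
#' @param polarity `"bright"`, `"dark"` or `"auto"`.
#' @param min_area_px,connectivity,pad_px See [label_components()] and
#'   [extract_crops()].
#' @param histogram_bins Passed to [otsu_threshold()].
#' @return List with `threshold`, `polarity`, `mask`, `regions`, `crops`.
#' @export
segment_scene <- function(image, polarity = c("auto", "bright", "dark"),
                          min_area_px = 25L, connectivity = 8L,
                          pad_px = 8L, histogram_bins = 256L) {
  polarity <- match.arg(polarity)
  thr <- otsu_threshold(image, histogram_bins)
  if (polarity == "auto") {
    m_bright <- binarize(image, thr, "bright")
    polarity <- if (mean(m_bright) < 0.5) "bright" else "dark"
  }
  mask <- binarize(image, thr, polarity)
  regions <- label_components(mask, connectivity, min_area_px)
  crops <- extract_crops(image, regions, pad_px)
  list(threshold = thr, polarity = polarity, mask = mask,
       regions = regions, crops = crops)
}
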