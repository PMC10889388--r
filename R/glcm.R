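# Grey-level co-occurrence matrix construction and the 20-descriptor texture
# library.
#
# Conventions, fixed across the package:
#   * grey levels are quantized to NG uniform bins of the 16-bit range;
#   * in the descriptor formulas, level values run 1..NG (so the sum
#     distribution P_{x+y} is indexed k = 2..2NG and the difference
#     distribution P_{x-y} is indexed k = 0..NG-1);
#   * logarithms are base 2 and 0 * log 0 := 0;
#   * when a marginal standard deviation is zero the correlation-family
#     descriptors (correlation, information measure 1, maximal correlation)
#     return the sentinel 0 with a warning - a constant texture carries no
#     correlation information.

#' Quantize a 16-bit grid to NG grey levels
#'
#' Uniform binning of the full 16-bit range; monotone in the input.
#'
#' @param pixels Integer matrix on the 16-bit scale.
#' @param ng Number of grey levels (>= 2).
#' @return Integer matrix with values in `0 .. ng - 1`.
#' @export
quantize_grey <- function(pixels, ng = 32L) {
  if (ng < 2L) stop("ng must be >= 2")
  q <- pmin(pixels %/% (65536 / as.integer(ng)), as.integer(ng) - 1L)
  storage.mode(q) <- "integer"
  q
}

glcm_offset <- function(d, theta) {
  if (!theta %in% c(0, 45, 90, 135))
    stop("theta must be one of 0, 45, 90, 135 degrees")
  d <- as.integer(d)
  switch(as.character(theta),
         "0"   = c(0L, d),
         "45"  = c(-d, d),
         "90"  = c(-d, 0L),
         "135" = c(-d, -d))
}

#' Compute a grey-level co-occurrence matrix
#'
#' Counts ordered pixel pairs at displacement `d` along angle `theta`
#' (0 deg = along rows to the right, 90 deg = up) whose quantized levels are
#' `(i, j)`, optionally restricted to pairs with both pixels inside a mask,
#' and normalizes to a probability matrix. Symmetric pooling also counts the
#' reversed pair, making the matrix symmetric.
#'
#' @param quantized Integer matrix with values in `0 .. ng - 1`
#'   (see [quantize_grey()]).
#' @param ng Number of grey levels.
#' @param d Pixel displacement (default 5, the feature-extraction setting).
#' @param theta Angle in degrees: 0, 45, 90 or 135 (default 0).
#' @param symmetric Pool each pair with its reverse (default `TRUE`).
#' @param mask Optional 0/1 matrix; pairs are counted only when both pixels
#'   are foreground.
#' @return An object of class `"glcm"`: list with `p` (NG x NG probability
#'   matrix summing to 1), `levels`, `d`, `theta`, `symmetric`, `n_pairs`.
#' @export
compute_glcm <- function(quantized, ng, d = 5L, theta = 0,
                         symmetric = TRUE, mask = NULL) {
  h <- nrow(quantized); w <- ncol(quantized)
  if (any(quantized < 0L) || any(quantized >= ng))
    stop("quantized values must lie in [0, ng)")
  off <- glcm_offset(d, theta)
  dr <- off[1L]; dc <- off[2L]
  r0 <- max(1L, 1L - dr); r1 <- min(h, h - dr)
  c0 <- max(1L, 1L - dc); c1 <- min(w, w - dc)
  if (r0 > r1 || c0 > c1)
    stop("degenerate input: grid smaller than the requested offset")
  a <- quantized[r0:r1, c0:c1, drop = FALSE]
  b <- quantized[(r0 + dr):(r1 + dr), (c0 + dc):(c1 + dc), drop = FALSE]
  if (!is.null(mask)) {
    ma <- mask[r0:r1, c0:c1, drop = FALSE] != 0L
    mb <- mask[(r0 + dr):(r1 + dr), (c0 + dc):(c1 + dc), drop = FALSE] != 0L
    keep <- ma & mb
    a <- a[keep]; b <- b[keep]
  }
  if (length(a) == 0L)
    stop("degenerate input: no valid pixel pair under the mask/offset")
  counts <- tabulate(as.integer(a) * ng + as.integer(b) + 1L,
                     nbins = ng * ng)
  p <- matrix(counts, ng, ng, byrow = TRUE)  # row i = level of first pixel
  n_pairs <- length(a)
  if (symmetric) {
    p <- p + t(p)
    n_pairs <- 2L * n_pairs
  }
  structure(list(p = p / sum(p), levels = as.integer(ng), d = as.integer(d),
                 theta = theta, symmetric = symmetric, n_pairs = n_pairs),
            class = "glcm")
}

#' @export
print.glcm <- function(x, ...) {
  cat(sprintf("<glcm> %d levels, d=%d, theta=%d%s, %d pairs\n",
              x$levels, x$d, x$theta,
              if (x$symmetric) " (symmetric)" else "", x$n_pairs))
  invisible(x)
}

# base-2 entropy helper with 0 log 0 := 0
plogp <- function(p) {
  nz <- p > 0
  s <- numeric(length(p))
  s[nz] <- p[nz] * log2(p[nz])
  s
}

#' Marginal and derived quantities of a GLCM
#'
#' Computes the marginals `px`, `py`, their means and standard deviations,
#' the sum distribution `P_{x+y}` (k = 2..2NG), the difference distribution
#' `P_{x-y}` (k = 0..NG-1), the entropies `HX`, `HY`, `HXY`, the cross terms
#' `HXY1`, `HXY2` and the `Q` matrix of the maximal-correlation descriptor.
#' Level values are 1..NG.
#'
#' @param glcm A `"glcm"` object.
#' @param need Character vector of optional blocks to compute: any of
#'   `"sumdiff"`, `"cross"`, `"q"` (all by default). The marginal block is
#'   always computed.
#' @return List of intermediates.
#' @export
texture_intermediates <- function(glcm, need = c("sumdiff", "cross", "q")) {
  p <- glcm$p
  ng <- glcm$levels
  lev <- seq_len(ng)  # level values 1..NG
  px <- rowSums(p)
  py <- colSums(p)
  mux <- sum(lev * px)
  muy <- sum(lev * py)
  sigx <- sqrt(sum((lev - mux)^2 * px))
  sigy <- sqrt(sum((lev - muy)^2 * py))
  hx <- -sum(plogp(px))
  hy <- -sum(plogp(py))
  hxy <- -sum(plogp(p))
  out <- list(px = px, py = py, mux = mux, muy = muy, sigx = sigx,
              sigy = sigy, hx = hx, hy = hy, hxy = hxy)
  if ("sumdiff" %in% need) {
    isum <- as.vector(outer(lev, lev, `+`))       # 2 .. 2NG
    idiff <- as.vector(abs(outer(lev, lev, `-`))) # 0 .. NG-1
    p_sum <- numeric(2 * ng - 1L)   # index k - 1 for k in 2..2NG
    acc <- rowsum(as.vector(p), isum)
    p_sum[as.integer(rownames(acc)) - 1L] <- acc[, 1L]
    p_diff <- numeric(ng)           # index k + 1 for k in 0..NG-1
    acc <- rowsum(as.vector(p), idiff)
    p_diff[as.integer(rownames(acc)) + 1L] <- acc[, 1L]
    out$p_sum <- p_sum
    out$p_diff <- p_diff
  }
  if ("cross" %in% need) {
    pxpy <- outer(px, py)
    nz <- pxpy > 0
    out$hxy1 <- -sum(p[nz] * log2(pxpy[nz]))
    out$hxy2 <- -sum(plogp(pxpy))
  }
  if ("q" %in% need) {
    # Q(i,j) = sum_k p(i,k) p(j,k) / (px(i) py(k)), over the support
    q <- matrix(0, ng, ng)
    pos <- px > 0
    if (any(pos)) {
      wk <- ifelse(py > 0, 1 / py, 0)
      a <- sweep(p, 2L, wk, `*`)       # p(i,k)/py(k)
      q[pos, ] <- (a[pos, , drop = FALSE] / px[pos]) %*% t(p)
    }
    out$q <- q
  }
  out
}

TEXTURE_DESCRIPTOR_NAMES <- c(
  "contrast", "correlation", "energy", "homogeneity", "variance",
  "entropy", "sum_average", "sum_entropy", "sum_variance",
  "difference_variance", "difference_entropy",
  "info_correlation_1", "info_correlation_2", "max_correlation",
  "autocorrelation", "dissimilarity", "max_probability",
  "cluster_shade", "cluster_prominence", "inverse_difference"
)

#' Texture descriptors of a GLCM
#'
#' Computes the classical 20-descriptor texture library: the 14 Haralick
#' descriptors (contrast, correlation, energy, homogeneity, sum-of-squares
#' variance, entropy, sum average/entropy/variance, difference
#' variance/entropy, the two information measures of correlation and the
#' maximal correlation coefficient) plus autocorrelation, dissimilarity,
#' maximum probability, cluster shade, cluster prominence and inverse
#' difference. `energy` is the angular second moment `sum(p^2)` (no square
#' root). Five of these also go by alternative names in the older
#' literature: energy (E), entropy (H), correlation (C), local uniformity
#' (L, = homogeneity) and moment of inertia (I, = contrast); see
#' [eq_texture_features()].
#'
#' @param glcm A `"glcm"` object.
#' @param which Optional character vector of descriptor names to compute
#'   (subset of `TEXTURE_DESCRIPTOR_NAMES`); the expensive maximal
#'   correlation eigen-decomposition is skipped unless requested.
#' @return Named numeric vector.
#' @export
texture_descriptors <- function(glcm, which = NULL) {
  want <- if (is.null(which)) TEXTURE_DESCRIPTOR_NAMES else
    match.arg(which, TEXTURE_DESCRIPTOR_NAMES, several.ok = TRUE)
  p <- glcm$p
  ng <- glcm$levels
  lev <- seq_len(ng)
  need <- character(0)
  if (any(c("sum_average", "sum_entropy", "sum_variance",
            "difference_variance", "difference_entropy") %in% want))
    need <- c(need, "sumdiff")
  if (any(c("info_correlation_1", "info_correlation_2") %in% want))
    need <- c(need, "cross")
  if ("max_correlation" %in% want) need <- c(need, "q")
  it <- texture_intermediates(glcm, need)
  idiff <- abs(outer(lev, lev, `-`))
  out <- stats::setNames(numeric(length(want)), want)
  degenerate_sig <- it$sigx == 0 || it$sigy == 0
  for (nm in want) {
    out[nm] <- switch(nm,
      contrast = sum(idiff^2 * p),
      correlation = {
        if (degenerate_sig) {
          warning("constant texture: correlation set to 0")
          0
        } else {
          sum(outer(lev - it$mux, lev - it$muy) * p) / (it$sigx * it$sigy)
        }
      },
      energy = sum(p^2),
      homogeneity = sum(p / (1 + idiff^2)),
      variance = it$sigx^2,  # sum-of-squares variance, mu = marginal mean
      entropy = -sum(plogp(p)),
      sum_average = sum((2:(2 * ng)) * it$p_sum),
      sum_entropy = -sum(plogp(it$p_sum)),
      sum_variance = {
        mu_s <- sum((2:(2 * ng)) * it$p_sum)
        sum(((2:(2 * ng)) - mu_s)^2 * it$p_sum)
      },
      difference_variance = {
        kd <- 0:(ng - 1L)
        mu_d <- sum(kd * it$p_diff)
        sum((kd - mu_d)^2 * it$p_diff)
      },
      difference_entropy = -sum(plogp(it$p_diff)),
      info_correlation_1 = {
        denom <- max(it$hx, it$hy)
        if (denom == 0) {
          warning("constant texture: information correlation 1 set to 0")
          0
        } else {
          (it$hxy - it$hxy1) / denom
        }
      },
      info_correlation_2 = {
        val <- 1 - exp(-2 * it$hxy2 + 2 * it$hxy)
        sqrt(max(0, val))
      },
      max_correlation = {
        if (degenerate_sig) {
          warning("constant texture: maximal correlation set to 0")
          0
        } else {
          ev <- sort(Re(eigen(it$q, only.values = TRUE)$values),
                     decreasing = TRUE)
          sqrt(max(0, ev[2L]))
        }
      },
      autocorrelation = sum(outer(lev, lev) * p),
      dissimilarity = sum(idiff * p),
      max_probability = max(p),
      cluster_shade = sum((outer(lev, lev, `+`) - it$mux - it$muy)^3 * p),
      cluster_prominence = sum((outer(lev, lev, `+`) - it$mux - it$muy)^4 * p),
      inverse_difference = sum(p / (1 + idiff))
    )
  }
  out
}

#' Texture features under their equation-letter names
#'
#' The five descriptors that the older texture literature writes as single
#' letters: energy E, entropy H, correlation C, local uniformity L and
#' moment of inertia I. L is identical to the Table-style homogeneity
#' descriptor and I to contrast; this function simply relabels
#' [texture_descriptors()] output.
#'
#' @param glcm A `"glcm"` object.
#' @return Named numeric vector `c(E, H, C, L, I)`.
#' @export
eq_texture_features <- function(glcm) {
  d <- texture_descriptors(glcm, c("energy", "entropy", "correlation",
                                   "homogeneity", "contrast"))
  stats::setNames(d, c("E", "H", "C", "L", "I"))
}
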