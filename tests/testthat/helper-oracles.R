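# Independent oracles: deliberately naive reimplementations (explicit loops,
# no shared code with the package internals) used to cross-check the fast
# implementations.

# GLCM by brute-force enumeration of every ordered pixel pair.
oracle_glcm <- function(q, ng, d, theta, symmetric = TRUE, mask = NULL) {
  dr <- switch(as.character(theta), "0" = 0L, "45" = -d, "90" = -d,
               "135" = -d)
  dc <- switch(as.character(theta), "0" = d, "45" = d, "90" = 0L,
               "135" = -d)
  counts <- matrix(0, ng, ng)
  for (r in seq_len(nrow(q))) {
    for (c in seq_len(ncol(q))) {
      r2 <- r + dr; c2 <- c + dc
      if (r2 < 1 || r2 > nrow(q) || c2 < 1 || c2 > ncol(q)) next
      if (!is.null(mask) && (mask[r, c] == 0 || mask[r2, c2] == 0)) next
      i <- q[r, c] + 1L; j <- q[r2, c2] + 1L
      counts[i, j] <- counts[i, j] + 1
      if (symmetric) counts[j, i] <- counts[j, i] + 1
    }
  }
  counts / sum(counts)
}

# Straight transcription of the 20 texture descriptor formulas, all loops.
# Conventions shared with the package (documented there): level values
# 1..NG, logs base 2, 0 log 0 = 0, sentinel 0 for correlation-family
# descriptors when a marginal standard deviation or entropy vanishes.
oracle_descriptors <- function(p) {
  ng <- nrow(p)
  lg <- function(x) if (x > 0) log2(x) else 0
  px <- numeric(ng); py <- numeric(ng)
  for (i in 1:ng) for (j in 1:ng) {
    px[i] <- px[i] + p[i, j]
    py[j] <- py[j] + p[i, j]
  }
  mux <- sum((1:ng) * px); muy <- sum((1:ng) * py)
  sigx <- sqrt(sum(((1:ng) - mux)^2 * px))
  sigy <- sqrt(sum(((1:ng) - muy)^2 * py))
  p_sum <- numeric(2 * ng)   # index k in 2..2NG
  p_diff <- numeric(ng)      # index k+1 for k in 0..NG-1
  for (i in 1:ng) for (j in 1:ng) {
    p_sum[i + j] <- p_sum[i + j] + p[i, j]
    p_diff[abs(i - j) + 1] <- p_diff[abs(i - j) + 1] + p[i, j]
  }
  hx <- -sum(sapply(px, function(v) v * lg(v)))
  hy <- -sum(sapply(py, function(v) v * lg(v)))
  hxy <- 0; hxy1 <- 0; hxy2 <- 0
  for (i in 1:ng) for (j in 1:ng) {
    hxy <- hxy - p[i, j] * lg(p[i, j])
    hxy1 <- hxy1 - p[i, j] * lg(px[i] * py[j])
    hxy2 <- hxy2 - px[i] * py[j] * lg(px[i] * py[j])
  }
  out <- c(
    contrast = sum(sapply(1:ng, function(i)
      sum(sapply(1:ng, function(j) (i - j)^2 * p[i, j])))),
    correlation = if (sigx == 0 || sigy == 0) 0 else
      sum(sapply(1:ng, function(i) sum(sapply(1:ng, function(j)
        (i - mux) * (j - muy) * p[i, j])))) / (sigx * sigy),
    energy = sum(p^2),
    homogeneity = sum(sapply(1:ng, function(i)
      sum(sapply(1:ng, function(j) p[i, j] / (1 + (i - j)^2))))),
    variance = sum(sapply(1:ng, function(i)
      sum(sapply(1:ng, function(j) (i - mux)^2 * p[i, j])))),
    entropy = hxy,
    sum_average = sum((2:(2 * ng)) * p_sum[2:(2 * ng)]),
    sum_entropy = -sum(sapply(p_sum[2:(2 * ng)], function(v) v * lg(v))),
    sum_variance = NA,
    difference_variance = NA,
    difference_entropy = -sum(sapply(p_diff, function(v) v * lg(v))),
    info_correlation_1 = if (max(hx, hy) == 0) 0 else
      (hxy - hxy1) / max(hx, hy),
    info_correlation_2 = sqrt(max(0, 1 - exp(-2 * hxy2 + 2 * hxy))),
    max_correlation = NA,
    autocorrelation = sum(sapply(1:ng, function(i)
      sum(sapply(1:ng, function(j) i * j * p[i, j])))),
    dissimilarity = sum(sapply(1:ng, function(i)
      sum(sapply(1:ng, function(j) abs(i - j) * p[i, j])))),
    max_probability = max(p),
    cluster_shade = sum(sapply(1:ng, function(i)
      sum(sapply(1:ng, function(j) (i + j - mux - muy)^3 * p[i, j])))),
    cluster_prominence = sum(sapply(1:ng, function(i)
      sum(sapply(1:ng, function(j) (i + j - mux - muy)^4 * p[i, j])))),
    inverse_difference = sum(sapply(1:ng, function(i)
      sum(sapply(1:ng, function(j) p[i, j] / (1 + abs(i - j))))))
  )
  mu_s <- out["sum_average"]
  out["sum_variance"] <- sum(((2:(2 * ng)) - mu_s)^2 * p_sum[2:(2 * ng)])
  kd <- 0:(ng - 1)
  mu_d <- sum(kd * p_diff)
  out["difference_variance"] <- sum((kd - mu_d)^2 * p_diff)
  q <- matrix(0, ng, ng)
  for (i in 1:ng) for (j in 1:ng) for (k in 1:ng) {
    if (px[i] > 0 && py[k] > 0)
      q[i, j] <- q[i, j] + p[i, k] * p[j, k] / (px[i] * py[k])
  }
  out["max_correlation"] <- if (sigx == 0 || sigy == 0) 0 else {
    ev <- sort(Re(eigen(q, only.values = TRUE)$values), decreasing = TRUE)
    sqrt(max(0, ev[2]))
  }
  out
}

# Otsu by exhaustive search over all candidate splits, direct two-class
# variance computation.
oracle_otsu <- function(px, nb = 256L) {
  width <- 65536 / nb
  bins <- pmin(as.vector(px) %/% width, nb - 1)
  best_t <- NA; best_v <- -Inf
  for (t in 0:(nb - 2)) {
    lower <- bins <= t
    w0 <- mean(lower)
    if (w0 == 0 || w0 == 1) next
    mu0 <- mean(bins[lower]); mu1 <- mean(bins[!lower])
    v <- w0 * (1 - w0) * (mu0 - mu1)^2
    if (v > best_v + 1e-12) { best_v <- v; best_t <- t }
  }
  (best_t + 1) * width - 1
}

# Per-class TP/FP/FN by explicit counting.
oracle_metrics <- function(truth, pred, classes) {
  res <- list()
  correct <- 0
  for (cl in classes) {
    tp <- fp <- fn <- 0
    for (i in seq_along(truth)) {
      if (truth[i] == cl && pred[i] == cl) tp <- tp + 1
      if (truth[i] != cl && pred[i] == cl) fp <- fp + 1
      if (truth[i] == cl && pred[i] != cl) fn <- fn + 1
    }
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    res[[cl]] <- c(precision = prec, recall = rec,
                   f1 = if (prec + rec > 0) 2 * prec * rec / (prec + rec)
                        else 0)
  }
  for (i in seq_along(truth)) if (truth[i] == pred[i]) correct <- correct + 1
  list(per_class = res, accuracy = correct / length(truth),
       macro_precision = mean(sapply(res, `[[`, "precision")),
       macro_recall = mean(sapply(res, `[[`, "recall")),
       macro_f1 = mean(sapply(res, `[[`, "f1")))
}

# random probability matrix for descriptor tests
random_glcm_object <- function(ng, seed, symmetric = FALSE) {
  set.seed(seed)
  m <- matrix(stats::rexp(ng * ng), ng, ng)
  if (symmetric) m <- m + t(m)
  structure(list(p = m / sum(m), levels = ng, d = 1L, theta = 0,
                 symmetric = symmetric, n_pairs = ng * ng),
            class = "glcm")
}

# small random quantized grid
random_grid <- function(seed, max_side = 32L, max_ng = 8L) {
  set.seed(seed)
  h <- sample(3:max_side, 1); w <- sample(3:max_side, 1)
  ng <- sample(2:max_ng, 1)
  list(q = matrix(sample(0:(ng - 1), h * w, TRUE), h, w), ng = ng)
}
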