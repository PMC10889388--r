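test_that("shape features of a filled rectangle", {
  m <- matrix(0L, 12, 22)
  m[2:11, 2:21] <- 1L
  sf <- shape_features(m)
  expect_equal(unname(sf["width"]), 20)
  expect_equal(unname(sf["height"]), 10)
  expect_equal(unname(sf["area"]), 200)
  expect_equal(unname(sf["extent"]), 1)
})

test_that("single-pixel region degenerates gracefully", {
  sf <- shape_features(matrix(c(0L, 0L, 0L, 1L), 2, 2))
  expect_equal(unname(sf["area"]), 1)
  expect_equal(unname(sf["extent"]), 1)
  expect_true(sf["compactness"] > 0 && sf["compactness"] <= 1.1)
})

test_that("a rasterized disk of radius 50 has compactness near 1", {
  dist <- outer(-60:60, -60:60, function(a, b) sqrt(a^2 + b^2))
  disk <- (dist <= 50) * 1L
  sf <- shape_features(disk)
  expect_gte(unname(sf["compactness"]), 0.95)
  expect_lte(unname(sf["compactness"]), 1.05)
})

test_that("Gabor statistics are DC-free and band-pass", {
  const <- matrix(30000L, 40, 40)
  g0 <- gabor_features(const)
  expect_equal(unname(g0["gabor_std"]), 0, tolerance = 1e-9)
  # intensity shift invariance
  set.seed(1)
  base <- matrix(as.integer(sample(10000:30000, 1600, TRUE)), 40, 40)
  g1 <- gabor_features(base)
  g2 <- gabor_features(base + 5000L)
  expect_equal(g1, g2, tolerance = 1e-9)
  # stronger response at the tuned frequency than far below it
  colpos <- outer(rep(1, 60), 1:60)  # value = column index
  tuned <- matrix(as.integer(30000 + 20000 *
                               sin(2 * pi * 0.25 * colpos)), 60, 60)
  detuned <- matrix(as.integer(30000 + 20000 *
                                 sin(2 * pi * 0.25 / 3 * colpos)), 60, 60)
  expect_gt(gabor_features(tuned)["gabor_mean"],
            gabor_features(detuned)["gabor_mean"])
  expect_error(gabor_features(matrix(0L, 5, 5)), "smaller")
})

test_that("LBP codes collapse on constant crops", {
  lf <- suppressWarnings(lbp_features(matrix(1000L, 10, 10)))
  expect_equal(unname(lf["lbp_energy"]), 1)
  expect_equal(unname(lf["lbp_entropy"]), 0)
})

test_that("LBP features equal the composition of verified parts", {
  set.seed(8)
  px <- matrix(as.integer(sample(0:65535, 400, TRUE)), 20, 20)
  lf <- lbp_features(px)
  codes <- lbp_codes(px)
  g <- compute_glcm(codes, ng = 256L, d = 1L, theta = 0, symmetric = TRUE)
  ref <- texture_descriptors(g, c("contrast", "correlation", "energy",
                                  "homogeneity", "entropy"))
  expect_equal(unname(lf),
               unname(ref[c("contrast", "correlation", "energy",
                            "homogeneity", "entropy")]))
})

test_that("LBP statistics are invariant to monotone rescaling", {
  set.seed(3)
  px <- matrix(sample(0:60000, 225, TRUE), 15, 15)
  f1 <- lbp_features(px)
  f2 <- lbp_features(px * 1.7 + 40)   # strictly monotone map
  expect_equal(f1, f2)
})

test_that("extract_features returns the 18 named attributes, deterministically", {
  sc <- render_scene(counts = c(PBP = 4L), image_shape = c(400L, 400L),
                     rng_seed = 12L)
  seg <- segment_scene(sc$image)
  fv <- extract_features(seg$crops[[1L]])
  expect_identical(names(fv), FEATURE_NAMES)
  expect_identical(fv, extract_features(seg$crops[[1L]]))
  expect_gt(fv[["area"]], 0)
  expect_true(fv[["extent"]] > 0 && fv[["extent"]] <= 1)
  expect_true(fv[["compactness"]] > 0 && fv[["compactness"]] <= 1.1)
  expect_true(fv[["glcm_asm"]] > 0 && fv[["glcm_asm"]] <= 1)
  expect_true(fv[["glcm_homogeneity"]] > 0 && fv[["glcm_homogeneity"]] <= 1)
})

test_that("features are invariant to crop translation", {
  sc <- render_scene(counts = c(PNA = 3L), image_shape = c(300L, 300L),
                     rng_seed = 23L)
  seg <- segment_scene(sc$image)
  cr <- seg$crops[[1L]]
  fv <- extract_features(cr)
  # embed the same content at a different offset inside a larger canvas
  bg <- as.integer(stats::median(cr$pixels[cr$mask == 0L]))
  for (off in list(c(0L, 0L), c(7L, 11L))) {
    canvas <- matrix(bg, nrow(cr$pixels) + 20L, ncol(cr$pixels) + 20L)
    mask <- matrix(0L, nrow(canvas), ncol(canvas))
    rr <- (1L + off[1L]):(nrow(cr$pixels) + off[1L])
    cc <- (1L + off[2L]):(ncol(cr$pixels) + off[2L])
    canvas[rr, cc] <- cr$pixels
    mask[rr, cc] <- cr$mask
    regs <- label_components(mask)
    crop2 <- extract_crops(canvas, regs, pad_px = 8L)[[1L]]
    fv2 <- extract_features(crop2)
    expect_equal(fv2, fv, tolerance = 1e-8)
  }
})

test_that("white and black classes share shape but differ in texture", {
  # benchmark seed density; same seed, so both scenes share seed geometry
  white <- render_scene(counts = c(PBP = 50L), rng_seed = 14L)
  black <- render_scene(counts = c(PNP = 50L), rng_seed = 14L)
  fw <- extract_feature_table(segment_scene(white$image)$crops)
  fb <- extract_feature_table(segment_scene(black$image)$crops)
  # same geometry specs: bounding boxes, area distributions close
  expect_equal(mean(fw$area), mean(fb$area), tolerance = 0.15)
  # intensity-driven GLCM statistics differ clearly
  expect_gt(abs(mean(fw$glcm_asm) - mean(fb$glcm_asm)) /
              stats::sd(c(fw$glcm_asm, fb$glcm_asm)), 1)
})
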