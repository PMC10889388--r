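---
title: "Methods: CFA seed classification, texture features, and the synthetic benchmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CFA seed classification, texture features, and the synthetic benchmark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedcfa)
```

# The problem and the data model

`seedcfa` classifies individual seeds into four classes — white and black
pepper crossed with two provenance phenotypes (`PBP`, `PBA`, `PNP`, `PNA`)
— from single-channel 16-bit rasters captured through a camera's color
filter array (CFA) and deliberately *not* demosaiced. A CFA raster carries
a 2×2-periodic gain texture (each photosite sees the scene through one
color filter), so absolute intensities alternate with pixel parity; texture
descriptors must either be robust to this raster or exploit statistics that
survive it. Working upstream of demosaicing avoids the smoothing that color
interpolation applies to exactly the high-frequency texture content that
distinguishes seed coats.

Images enter and leave the package as:

* PGM (P2 ASCII / P5 binary, maxval up to 65535, two-byte samples
  big-endian). 8-bit files are upcast to the 16-bit scale by multiplying by
  257 so that full scale maps to full scale; the original depth is
  recorded.
* 16-bit grayscale PNG for per-seed crops. The PNG encoder is implemented
  in-package (filter-0 scanlines, one zlib IDAT) because the installed
  raster stack only writes 8-bit PNGs; decoding in tests goes through
  `png::readPNG`, which does handle 16 bits.

Coordinates are 1-based `(row, col)` and bounding boxes are inclusive at
both ends — the host language's native convention; keeping a single
convention everywhere matters more than which one is picked.

# Segmentation

Scenes are thresholded with Otsu's criterion on a 256-bin histogram of the
16-bit range. Using 256 bins rather than 65536 stabilizes the between-class
variance curve (a full-depth histogram of a single frame is mostly empty
bins) and mirrors the grey-level compression used for texture work. The
threshold is the bin edge maximizing between-class variance; ties resolve
to the lowest edge, which places the cut directly above the background
cluster when a gap separates background from seeds.

Polarity `"auto"` picks the mask orientation whose foreground occupies less
than half the frame, since seeds are sparse objects on a uniform ground.
Components are labelled 8-connected (diagonally touching seed pixels belong
together), and components below `min_area_px = 25` are discarded as CFA
speckle. No morphological opening or closing is applied by default; a
global threshold plus the area filter suffices for well-separated seeds.
Touching-seed splitting (watershed) is out of scope: acquisition spreads
seeds by hand.

**A real limitation worth knowing.** The Bayer gains split the *background*
into three intensity spikes. When dark-class seeds (interior ≈ 0.25 of full
scale against a 0.08 background) occupy only a fraction of a percent of the
frame, the between-class variance of the background's own structure can
exceed that of the tiny foreground, and the global threshold locks onto the
wrong gap. At the benchmark's areal density (about 50 seeds per 1024×1024
frame) the foreground always wins and recovery is exact; the scene
simulator therefore scales frame size with seed count
(`scene_shape_for()`), emulating a fixed camera over a standard pinch of
seeds. Bright classes are immune (their contrast is far above the
guarantee), and dark-seed *coverage* still loses a few percent of
texture-trough pixels on the lowest-gain photosites without affecting seed
identity or boxes.

# The 18 attributes

Four groups, fixed order (`FEATURE_NAMES`):

**Shape** (from the region mask): `area` (pixel count); `perimeter` — the
length of the traced 8-connected outer boundary chain with
Vossepoel–Smeulders step weights (0.948 per axial, 1.340 per diagonal
step); `compactness` = 4πA/P², normalized to 1 for a disk; `extent` =
area over bounding-box area; `width`, `height`. The corrected chain
weights matter: the naive 1/√2 chain overestimates a smooth contour by
about 5% on average over orientations, which would bias a disk's
compactness to ≈ 0.90. With the corrected weights a rasterized disk of
radius 50 lands within 5% of compactness 1 (this is asserted in the test
suite). A single-pixel region uses the unit-square perimeter 4.

**Gabor**: mean and standard deviation of the magnitude response to one
fixed complex Gabor kernel — orientation 0°, frequency 0.25 cycles/px,
Gaussian σ = 3 px, support 19×19, coefficient sum exactly zero so the
response is invariant to intensity shifts. One fixed, documented filter
(rather than a multi-scale bank) keeps the attribute count at two; 0.25
cycles/px sits between the two synthetic texture frequencies and inside
the band of natural seed-coat texture at this magnification. Crops are
padded by 8 px at extraction so the smallest legitimate seed still admits
a valid (un-padded) convolution window.

**LBP**: rotation-variant 8-bit local-binary-pattern codes (P = 8, R = 1;
bit k set when the k-th neighbour ≥ centre), then a symmetric distance-1,
0° co-occurrence matrix over the 256 code values, from which contrast,
correlation, energy, homogeneity and entropy are read. The code image
depends only on intensity *ranks*, so these five statistics are invariant
to any strictly monotone intensity transform — a useful property under
per-photosite gain. Building a GLCM *of the code image* (rather than a
plain code histogram) retains spatial arrangement of the micro-patterns;
the alternative histogram reading would discard it, and homogeneity/
contrast of a bare histogram are not even defined.

**GLCM**: the co-occurrence matrix `P(i,j | d, θ)` of the 32-level
quantized crop, restricted to pixel pairs inside the seed mask, at the
production offset d = 5, θ = 0°, with symmetric pooling. d = 1 with all
four angles (0°, 45°, 90°, 135°) is available through `feature_config()`
— the general exposition setting — but the extractor's default follows the
production run. 32 levels balances co-occurrence matrix density against
level discriminability for crops of a few hundred pixels. For very narrow
seeds the masked matrix can have no pair at lag 5; the extractor then
falls back to the unmasked crop rather than failing the seed.

## The 20-descriptor texture library

`texture_descriptors()` computes the classical library from any
co-occurrence matrix: contrast, correlation, energy (= angular second
moment Σp², no square root anywhere), homogeneity, sum-of-squares
variance, entropy, sum average, sum entropy, sum variance, difference
variance, difference entropy, the two information measures of correlation,
the maximal correlation coefficient (√ of the second-largest eigenvalue of
the Q matrix), autocorrelation, dissimilarity, maximum probability,
cluster shade, cluster prominence and inverse difference. The five
single-letter names of the older literature (E, H, C, L, I — energy,
entropy, correlation, local uniformity, moment of inertia) are aliases of
energy, entropy, correlation, homogeneity and contrast respectively
(`eq_texture_features()`).

Numerical conventions, applied uniformly and mirrored by the brute-force
transcription oracle in the test suite:

* grey-level *values* are 1..NG, so the sum distribution is indexed
  k = 2..2NG and the difference distribution k = 0..NG−1;
* logarithms are base 2 and 0·log 0 := 0;
* when a marginal standard deviation (or entropy) is zero — a constant
  texture — the correlation-family descriptors (correlation, information
  measure 1, maximal correlation) return 0 with a warning instead of NaN:
  a constant texture carries no correlation information;
* the marginals, means and variances enter through exact summations of the
  normalized matrix; Σp = 1 is maintained to 1e−12 after every build.

# Cleaning, scaling, selection

**Isolation forest** (in-package: 100 trees, subsample 256, split features
and split points uniform at random, score 2^(−E[h]/c(ψ))): rows are scored
per class batch — batches are curated separately, and a class with
systematically larger seeds should not have its tail amputated by another
class's geometry — and the most anomalous `round(0.05 · n)` rows of each
batch are dropped. With the four batch sizes 1335/1416/1437/1430 this
removes 67 + 71 + 72 + 72 = 282 rows, i.e. exactly a 5% trim of 5618.

**Robust scaling**: per column, subtract the median and divide by the IQR
(Q3 − Q1, quartiles by linear interpolation — `stats::quantile` type 7).
Columns with zero IQR divide by 1, mapping constants to 0. The scaler is
fitted on training rows only and applied to both partitions.

**Selectors** (all return subsets of the 18 names):

* variance threshold 0.02 on the scaled training data;
* chi-squared top-5: each column is shifted by its minimum to be
  non-negative (scaled attributes are routinely negative, and the statistic
  requires non-negative mass), then the χ² statistic of per-class column
  sums against the class-frequency expectation ranks the columns;
* SGD importance: one-vs-rest linear hinge classifier; importance of a
  column is the mean absolute coefficient across classes; keep columns at
  or above the mean importance;
* RFECV: per CV fold, recursively drop the lowest-importance column and
  score every column count on the held-out fold; the best mean accuracy
  wins, ties going to the smaller count; a final elimination pass on all
  rows returns that many columns;
* ANOVA: per-column one-way F-test across the four classes, keep p < 0.05,
  no multiplicity correction (each column is judged on its own).

The full pipeline orders these as clean → split → scale (fit on train) →
select, so no test-row statistic leaks into scaling or selection.

# Models and evaluation

Four classifiers behind one interface (`train_predict()`): k-nearest
neighbours (`class::knn`, Euclidean majority vote), the in-package
Pegasos-style linear hinge SGD (one-vs-rest, intercept as an appended
constant feature, η_t = 1/(αt), 20 epochs, final-epoch averaging — also the
engine behind the two model-based selectors), a kernel SVM (`e1071::svm`;
`gamma = "scale"` uses the 1/(p·Var x) heuristic) and a random forest
(`randomForest`). Seeded models are deterministic given the seed; all
randomness flows from one integer through counter-based seed derivation,
never through global RNG state.

Grid search is exhaustive over documented grids — KN k ∈ {3,5,7,11}; SGD
α ∈ {1e−4,1e−3,1e−2}; SVM kernel ∈ {linear, radial} × C ∈ {0.1,1,10,100} ×
γ ∈ {scale, 0.01, 0.1}; RF trees ∈ {100,300} × depth ∈ {∅,10,20} — with
5-fold CV on the training partition only, ties to the first grid row. Both
SVM kernels stay in the grid because the production choice between linear
and RBF is genuinely ambiguous; on the synthetic benchmark the linear
kernel usually wins the tie at equal CV accuracy by grid order.

The split is stratified 80/20 with `ceiling(n · 0.2)` test rows
apportioned by largest remainder (a 5336-row table yields 4268/1068).
Metrics are macro-averaged: per-class precision and recall from the
confusion matrix (class order PBP, PBA, PNP, PNA everywhere), per-class F1
by the harmonic formula, unweighted means across classes. A class never
predicted receives precision 0. Learning curves refit the model on growing
prefixes of each fold's shuffled training rows and report mean train and
validation accuracy per size.

# The synthetic benchmark

`render_scene()` draws each seed as an ellipse (major semi-axis uniform in
the class's radius range, axis ratio uniform in its range, orientation
uniform) whose interior is the class mean intensity plus a horizontal
sinusoid (class frequency, random phase) plus Gaussian grain
(σ = 0.02 of full scale), placed without overlap with a 6 px halo; the
frame is multiplied by the RGGB gain quartet (0.8, 1.0, 1.0, 0.7) and
quantized to 16 bits. Class design:

| class | mean | texture freq (c/px) | amplitude | axis ratio |
|-------|------|--------------------|-----------|------------|
| PBP   | 0.75 | 0.20               | 0.10      | 0.55–0.70  |
| PBA   | 0.75 | 0.12               | 0.10      | 0.75–0.90  |
| PNP   | 0.25 | 0.20               | 0.06      | 0.55–0.70  |
| PNA   | 0.25 | 0.12               | 0.06      | 0.75–0.90  |

The white/black split is an easy intensity contrast; the within-color
split rests only on texture frequency and eccentricity, the structure the
Gabor, lag-5 GLCM and shape attributes are positioned to resolve. Dark
amplitudes are smaller so interiors stay well above the 0.08 background.
Radii (10–16 px major semi-axis) give seeds of roughly 150–600 px, large
enough for every attribute to be defined and small enough that a
50-seed scene fits a 1024×1024 frame at the fixed density discussed above.

The default benchmark is 500 seeds per class (2000 seeds across 40
scenes), extracted, cleaned at contamination 0.05, scaled, split 80/20 and
graded with the grid-searched SVM. These sizes were chosen as the smallest
round benchmark at which all pipeline stages operate in their intended
regime; the test suite uses the same generator at smaller sizes for
stage-level checks.

**What the generator does and does not emulate.** It reproduces the
features the pipeline actually consumes: a mosaiced single-channel raster,
bright/dark blobs with controlled intra-seed texture, exact ground truth.
It does not attempt photorealism: no optical point-spread function, no
illumination gradient or vignetting, no shadows, no seed-surface
speckle beyond stationary sinusoid-plus-noise, no touching seeds.
Consequently, passing the benchmark demonstrates that the pipeline's
machinery — segmentation geometry, feature mathematics, leakage-free
tabular flow, model tuning — is correct and that the advertised accuracy
is attainable under the stated contrasts; it does not certify accuracy on
any particular physical seed collection, where class overlap is driven by
biology rather than by four designed parameters. The synthetic benchmark's
near-perfect separability is the expected outcome of its construction, and
the acceptance bound on it is a lower-bound sanity check, not an estimate
of field performance.

# Degenerate inputs and tie-breaks

* Constant images: Otsu refuses (no two-class structure); callers decide
  policy.
* Otsu ties: lowest bin edge; grid-search ties: first row in grid order;
  RFECV ties: fewer columns.
* GLCM with no valid pair (offset larger than grid, or empty mask
  intersection): error at the API; the feature extractor falls back to the
  unmasked crop for narrow seeds.
* Zero-IQR columns scale by 1; zero-σ textures return sentinel 0 for
  correlation-family descriptors with a warning.
* `sample_feature_table(class_shift = 0)` is an exchangeable null: all
  selector calibration tests (ANOVA keep-rate ≈ α, permutation-test
  non-significance) run against it.

# Known limitations

* Camera RAW (.RAF) decoding is out of scope; the pipeline starts at PGM.
* A single global threshold cannot rescue extremely sparse dark-seed
  scenes (see Segmentation); constant-density simulation reflects the
  intended acquisition geometry.
* The LBP statistic family is one of two defensible readings (GLCM of the
  code image vs. histogram statistics); the spatial reading implemented
  here is the stricter one, and the choice is isolated in
  `lbp_features()`.
* Learning-curve estimates at the smallest sizes can be undefined for a
  fold that lacks a class; scores average over the folds that are defined.
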