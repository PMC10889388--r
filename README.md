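# seedcfa

Classification of pepper seed types from undemosaiced color-filter-array
(CFA) camera images.

Authenticating premium seed lots — for example separating Penja-grown
*Piper nigrum* from visually similar imports — is hard by eye: the seeds
share shape, size and surface texture. `seedcfa` implements a complete
machine-vision pipeline for this problem operating directly on the 16-bit
single-channel raster a camera sensor records *before* demosaicing.
Working on the raw CFA mosaic preserves the fine texture statistics that
color interpolation smears out, at the cost of a 2×2-periodic Bayer gain
pattern that every downstream stage has to tolerate.

The pipeline stages, each exposed as ordinary R functions:

1. **Imaging** — PGM (P2/P5, 8/16-bit, big-endian) reader/writer and a
   16-bit grayscale PNG writer for per-seed crops.
2. **Segmentation** — Otsu thresholding on a 256-bin histogram of the
   16-bit range, binary masks, 8-connected component labeling, bounding
   boxes and padded crops.
3. **Features** — an 18-attribute vector per seed:
   - *shape*: area, perimeter, compactness `4πA/P²`, extent, width, height;
   - *Gabor*: mean and standard deviation of the magnitude response to a
     fixed zero-DC complex Gabor kernel (0°, 0.25 cycles/px, σ = 3 px);
   - *LBP*: contrast, correlation, energy, homogeneity and entropy of a
     grey-level co-occurrence matrix built on the local-binary-pattern code
     image (P = 8, R = 1);
   - *GLCM*: dissimilarity, correlation, contrast, homogeneity and angular
     second moment of the co-occurrence matrix
     `P(i,j | d = 5, θ = 0°)` at 32 grey levels.
   The full 20-descriptor texture library (Haralick's 14 plus
   autocorrelation, dissimilarity, maximum probability, cluster shade,
   cluster prominence, inverse difference) is available through
   `texture_descriptors()`.
4. **Tabular** — isolation-forest outlier removal per class batch
   (contamination 0.05), robust median/IQR scaling, and five feature
   selectors: variance threshold (0.02), chi-squared top-k (k = 5), linear
   SGD importance (mean threshold), recursive feature elimination with
   cross-validation, and per-column ANOVA F-tests (α = 0.05).
5. **Models** — stratified 80/20 split, exhaustive grid search with 5-fold
   CV, and four classifiers: k-nearest neighbours, a linear hinge-loss SGD
   classifier, an SVM and a random forest; evaluation via accuracy, macro
   precision/recall/F1, confusion matrices and learning curves.

Because real seed image collections are rarely redistributable, the package
ships a first-class synthetic scene generator: four seed classes (white and
black crossed with two texture/shape phenotypes, labelled PBP/PBA/PNP/PNA)
rendered as textured elliptical blobs through a simulated RGGB Bayer raster,
with exact ground truth (counts, boxes, labels). Every stage of the package
is tested against it.

## Worked example

```r
library(seedcfa)

# a synthetic scene of 10 black Penja-like seeds
sc <- render_scene(counts = c(PNP = 10L),
                   image_shape = scene_shape_for(10), rng_seed = 7L)
sc$image
#> <cfa_image> 458 x 458, 16-bit, range [3670, 23833], origin: synthetic

seg <- segment_scene(sc$image)
# threshold 9727 (bright polarity), 10 seeds found

round(extract_features(seg$crops[[1]])[
  c("area", "perimeter", "compactness", "gabor_mean",
    "glcm_correlation", "glcm_asm")], 3)
#>             area        perimeter      compactness       gabor_mean
#>          185.000           52.332            0.849            0.770
#> glcm_correlation         glcm_asm
#>           -0.099            0.051
```

The first seed covers 185 pixels with near-circular compactness 0.849; its
GLCM correlation at lag 5 is slightly negative (the intra-seed texture
period does not match the 5-pixel offset) and the angular second moment
0.051 reflects the narrow intensity spread of a dark seed.

Running the tabular and modelling half on a 400-seed benchmark:

```r
ft <- synthetic_benchmark_features(per_class = 100L, rng_seed = 42L)
res <- run_tabular_models(ft, pipeline_config(models = c("kn", "svm"),
                                              rng_seed = 42L))
res$reports$svm
#> <eval_report> model: SVM, n = 76
#>   accuracy 1.000 | macro precision 1.000 | recall 1.000 | F1 1.000
#>   confusion (rows = truth):
#>      predicted
#> truth PBP PBA PNP PNA
#>   PBP  19   0   0   0
#>   PBA   0  19   0   0
#>   PNP   0   0  19   0
#>   PNA   0   0   0  19
```

After cleaning (5% contamination per batch) and robust scaling, the tuned
SVM separates all four classes of the synthetic benchmark; the easy
black/white split and the texture-borne within-color split are both
resolved.

A thin command-line front end mirrors the stages
(`inst/exec/seedcfa <simulate|extract|features|clean|select|train|run>`).

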