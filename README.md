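# epiquant

Quantitative protein assays on tissue lysates (ELISA, arrays, mass
spectrometry) are confounded by tissue composition: tumor-bearing prostate
specimens contain far more epithelium than benign ones, so an "elevated"
epithelial protein may reflect nothing but the extra epithelium. `epiquant`
estimates the **epithelium percentage** of an H&E-stained section with a
color-based grid-cell classifier and uses it to normalize per-case assay
concentrations, separating tissue composition from biological expression.

It is aimed at researchers doing quantitative proteomics or immunoassays on
solid-tissue specimens who have routine H&E sections of the same tissue.

## Method at a glance

For a micrograph of an H&E section:

1. **Four-color segmentation.** Pixels are clustered by k-means (squared
   Euclidean distance on RGB, Lloyd's algorithm, k-means++-style seeding,
   best of `n_init` restarts) into the stain's four dominant colors — white
   (lumen), light and dark pink (stroma), purple (epithelium) — named by
   luminance rank. Fitting is per image, absorbing slide-to-slide staining
   variation.
2. **Grid cells.** The image is tiled into 20 × 20 px cells (0.04 × 0.04 mm²
   at 2 µm/px). Each cell's feature is its color-area ratio vector; the four
   ratios are closed (sum to 1), so three of them span the feature space.
3. **Tissue classification.** From one manually annotated training image,
   cells are labeled *luminal* (white ratio > 0.70, regardless of
   annotation), *epithelial* (≥ 50% annotated coverage) or *stromal*; class
   centroids are placed in ratio space and every cell is classified by
   nearest centroid.
4. **Epithelium percentage.**

   ```
   epithelium % = 100 × epithelial area / (epithelial + stromal area)
   ```

   computed from cell counts, lumen excluded; case-level values pool cell
   counts over all of a case's tiles.
5. **Assay normalization.** Each case's concentration (ng per mg total
   protein) is divided by its epithelium fraction; groups are compared with
   the two-sided unpaired Wilcoxon rank-sum test and summarized as fold
   changes of group means.

A synthetic-micrograph generator (gland-like purple annuli with white lumens
on a two-tone pink stroma, per-pixel ground truth, controllable color noise)
makes the whole pipeline testable without slides; `cross_validate()`
reproduces the held-out cell evaluation (accuracy / false positives / false
negatives, which always sum to 100%, and the predicted-vs-marked epithelial
area R²).

## Worked example

Two synthetic "cases" — a benign-like slide (25% target epithelium) and a
tumor-like slide (60%) — run through the full pipeline, training on the
annotated tumor slide:

```r
library(epiquant)

specs <- lapply(c(normal = 0.25, tumor = 0.60), function(f)
  synthetic_spec(target_epithelium_fraction = f,
                 gland_count = max(2, round(16 * f)),
                 seed = round(100 * f)))
slides <- lapply(specs, generate_micrograph)

res <- epithelium_pipeline(slides, training_index = 2, seed = 42)
res$estimates[, c("image_id", "n_epithelial", "n_stromal", "n_luminal",
                  "epithelium_percent", "truth_percent")]
#>   image_id n_epithelial n_stromal n_luminal epithelium_percent truth_percent
#> 1 image_01           65       157        34           29.27928      27.90308
#> 2 image_02          142        81        33           63.67713      60.37050
```

Each row is one slide: cell counts per tissue class, the estimated
epithelium percentage, and (synthetic data only) the pixel-level truth — the
estimates land within a few points of truth. Normalizing ELISA-like
concentrations by the estimated fractions:

```r
meas <- data.frame(case_id = c("N1", "T1"), group = c("normal", "tumor"),
                   analyte = "EpCAM", concentration = c(9.4, 44.6),
                   epi_fraction_computer = res$estimates$epithelium_percent / 100)
normalize_by_epithelium(meas)[, c("case_id", "group", "concentration",
                                  "normalized_value")]
#>   case_id  group concentration normalized_value
#> 1      N1 normal           9.4         32.10462
#> 2      T1  tumor          44.6         70.04085
```

The raw 4.7-fold difference shrinks to about 2-fold once the tumor's higher
epithelium content is accounted for — the compositional part of the signal
is gone, the biological part remains.

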