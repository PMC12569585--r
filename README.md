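# glandsurv

Gland morphology predicts outcome in colorectal cancer: the degree of gland
formation defines tumour grade, and glands become deformed as cancer
progresses. `glandsurv` implements a complete, testable version of the
pipeline that turns that observation into a prognostic model:

1. **Contour-aware gland instance segmentation.** A two-branch
   convolutional network (shared encoder; separate gland-object and
   gland-contour decoders fused from multiple scales by bilinear
   upsampling, with discounted deep supervision) predicts per-pixel
   probability maps. Fusing them — foreground iff
   `P(object) >= t_o` and `P(contour) < t_c` — cuts touching glands apart;
   cleanup removes regions under 400 px (strict), smooths with a radius-3
   disk, fills holes, and regrows the separated cores. A plain U-Net is
   included as the single-branch baseline.
2. **Vahadane-style stain normalization.** Beer–Lambert optical densities
   `OD = -log10((I+1)/256)` are factorized as `V ≈ W H` with a non-negative
   unit-column 3×2 stain dictionary and sparse concentrations; patches are
   normalized by recombining rescaled concentrations with a target
   dictionary.
3. **GlaS-style object-level evaluation.** Detection F1 (a prediction is a
   true positive iff it covers **more than** 50 % of a ground-truth
   object's area), object-level Dice

   `D = ½ [ Σᵢ ωᵢ d(Gᵢ, P(Gᵢ)) + Σⱼ ω̃ⱼ d(Pⱼ, G(Pⱼ)) ]`,

   and the area-weighted object-level Hausdorff distance on boundary point
   sets.
4. **Whole-image inference.** Otsu tissue masking, non-overlapping 500-px
   tiles at 20× (40× inputs are downsampled by 2), per-tile
   normalize → predict → fuse → clean, stitching with seam-aware instance
   merging.
5. **Morphometry.** The 13 per-gland shape descriptors (area, axis
   lengths, eccentricity, orientation, convex/filled area, equivalent
   diameter, solidity, extent, perimeter, box aspect ratio, compactness)
   aggregated per patient with 6 statistics (mean, median, sd, skewness,
   kurtosis, max) into a 78-column patient vector.
6. **Survival modelling.** Ridge-penalized Cox proportional hazards
   (Efron ties, Newton with step-halving), Harrell's concordance index,
   5-fold cross-validation with per-fold standardization, median-split
   risk stratification, Kaplan–Meier curves and the two-sample log-rank
   test.

Everything runs on synthetic data: the package ships a gland-image
generator (deformed-ellipse glands with lumens, touching instances, H&E
coloration with stain variation) and a cohort generator whose survival
times follow a known Weibull-baseline Cox model driven by measured gland
morphology — so the full pipeline is exercised end-to-end without any
external download.

## Worked example

```r
library(glandsurv)

# synthesize a tile and segment it with a freshly trained desk-scale model
train <- lapply(1:40, function(i) {
  reg <- if (i %% 2 == 0) gland_regime("deformed") else gland_regime("regular")
  simulate_gland_image(96, 96, reg, n_glands = 3 + (i %% 3), seed = 100 + i)
})
cfg <- train_config(learning_rate = 0.5, momentum = 0.9, grad_clip = 0.5,
                    batch_size = 4, epochs = 40, patch_size = 96,
                    crop_size = 96, seed = 42)
model <- train_model(build_model("dcan", width_multiplier = 0.125, seed = 42),
                     train, cfg)

test <- simulate_gland_image(96, 96, gland_regime("deformed"), 4, seed = 9002)
lab <- segment_probability_pair(predict_probs(model, test$image),
                                min_area = 100, smooth_radius = 2)
segmentation_score(lab, test$truth)
#> # A tibble: 1 × 6
#>      f1 object_dice object_hausdorff    tp    fp    fn
#>   <dbl>       <dbl>            <dbl> <int> <int> <int>
#> 1     1       0.978                1     4     0     0
```

F1 = 1 means all 4 true glands were detected with no spurious
predictions; object Dice 0.98 and a mean object Hausdorff of 1 px say the
recovered gland shapes match the ground truth closely.

```r
# survival: synthetic cohort whose hazard is driven by gland shape
co <- simulate_cohort(cohort_spec(n_patients = 300, seed = 11))
cv <- cox_cross_validate(co$patients[, c("patient_id", patient_feature_names())],
                         co$survival, k = 5, ridge_penalty = 1, seed = 3)
glance(cv)
#> # A tibble: 1 × 5
#>       k mean_c_index sd_c_index lambda  seed
#>   <dbl>        <dbl>      <dbl>  <dbl> <dbl>
#> 1     5        0.815     0.0357      1     3

strat <- stratify_risk(cv$risk)
logrank_test(co$survival, strat$group)$p_value
#> [1] 7.799069e-35
autoplot(kaplan_meier(co$survival, strat$group))
```

A mean out-of-fold C-index of 0.82 (0.5 = random, 1 = perfect) and a
log-rank p-value far below 0.05 show that morphology-driven risk scores
separate the median-split strata sharply — the cohort was generated with
oracle concordance ≈ 0.85, so 0.82 is close to the attainable ceiling.

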