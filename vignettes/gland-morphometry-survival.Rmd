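---
title: "From gland shape to survival: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From gland shape to survival: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`glandsurv` implements a histology-to-outcome pipeline for colorectal
cancer: segment every gland in an H&E image with a contour-aware network,
describe each gland with 13 shape features, aggregate them per patient,
and model overall survival with a ridge-penalized Cox proportional-hazards
regression. This vignette records the models, the assumptions behind
them, and the decisions taken where the design was genuinely open. It
states no empirical result beyond what the package's tests and
`scripts/acceptance.R` themselves compute.

## The segmentation model

Gland segmentation is an *instance* problem: malignant glands deform
dramatically, and neighbouring glands touch, so plain foreground
segmentation merges them. The contour-aware model uses one downsampling
encoder (4 levels, 3×3 convolutions, 2×2 max-pooling) and two upsampling
branches. Each branch attaches a 1×1 classifier to encoder levels 2–4,
bilinearly upsamples the per-level score maps to full resolution and sums
them; the per-level maps are kept as auxiliary outputs for deep
supervision. One branch predicts gland objects, the other gland contours.
The loss is

```
L = CE(object) + CE(contour) + w(epoch) * sum_l [CE_aux_l(object) + CE_aux_l(contour)]
```

with `w` decaying linearly from 1 to 0 over the first half of training
(the discount schedule is otherwise unconstrained; linear-to-half is the
simplest non-increasing choice). A conventional U-Net (same encoder,
skip-connected decoder, single object output) is included as the
single-branch baseline.

Contour targets are built from the instance ground truth: the boundary of
each instance (pixels 4-adjacent to anything that is not the instance,
which includes the interface between touching glands) dilated with a disk
of radius 2 px — the paper-silent thickness default at 20×
magnification. Because inter-gland interfaces are included, subtracting
confident contour pixels from the object mask always separates touching
instances.

### Numerical choices in the network

The implementation is self-contained (im2col convolutions, 2×2 max
pooling, integer-factor bilinear upsampling with its exact adjoint, all
verified against finite differences). Three choices matter for anyone
retraining it:

* **Leaky rectifier (slope 0.01).** The nets carry no normalization
  layers; with hard ReLUs, SGD at useful learning rates can push an
  entire layer's pre-activations negative, after which all weight
  gradients vanish and training collapses to predicting class priors.
  The 1 % leak keeps gradient flowing.
* **Zero-initialized classifier heads.** Encoder weights are
  Xavier-uniform from a fixed seed; the 1×1 classifier heads start at
  zero so initial logits are neutral rather than large random sums of
  three upsampled score maps.
* **Per-layer gradient clipping** (norm cap, default 1; desk runs use
  0.5). Classifier heads and deep encoder layers have gradient magnitudes
  that differ by orders of magnitude; a shared learning rate either
  stalls the heads or destabilizes the encoder. Capping each layer's
  gradient norm lets one rate serve both. The optimizer remains plain
  SGD (with optional momentum).

Training defaults follow the full-scale recipe (learning rate 1e-4, batch
4, 500-px patches with random 480-px crops, rotations in {0°, 90°, 180°,
270°}, horizontal flips at p = 0.5, 78 epochs). The *desk-scale* recipe
used throughout the tests and the acceptance script — width multiplier
0.125 (4/8/16/32 channels), 96×96 tiles, learning rate 0.5 with momentum
0.9 and clip 0.5, 40 epochs on 40 images — was chosen once as the
smallest configuration whose training reliably converges on the synthetic
task; the vignette's problem sizes (40 training / 10 held-out tiles, one
1500×1500 whole image, 300-patient cohorts) are the package's own
desk-scale study conditions.

### Post-processing

Fusion marks a pixel foreground iff `P(object) >= 0.5` and
`P(contour) < 0.5` (both thresholds exposed; the method's description
names none, so the neutral 0.5/0.5 is the default). Cleanup then:

1. removes 4-connected components **strictly** below 400 px (a 400-px
   component is kept — the rule reads "less than");
2. applies morphological closing-then-opening with a disk of radius 3
   (the disk-filter smoothing is interpreted morphologically because that
   preserves binarity by construction; close–open is an idempotent
   morphological filter, which is why repeated cleanup is stable);
3. fills holes per component;
4. re-applies the minimum-area rule (the removal/smoothing order is
   stated both ways in the method's two descriptions; removing again
   after smoothing satisfies both readings).

Because fusion subtracts the contour band, cleaned instances are eroded
cores; `segment_probability_pair()` therefore regrows each core into the
plain thresholded object mask by iterative 4-neighbour region growing
(ties to the lower label — deterministic), and the 400-px rule binds the
final grown instances while cores need only a quarter of it. Without the
reduced core floor, any gland whose eroded core dips below the full
threshold vanishes before it can regrow.

4-connectivity is used for labelling throughout (diagonal contacts stay
separate, consistent with contour-based separation). The 400-px rule is
applied in pixels as written, even though 0.465 vs 0.55 µm/px scanners
differ by ~40 % in area per pixel — a caveat inherited from the method.

## Stain normalization

Structure-preserving normalization factorizes tissue optical densities
(`OD = -log10((I+1)/256)`; the `+1` makes the transform total and exactly
invertible on 8-bit data) as `V ≈ W H`, with `W` a non-negative 3×2
dictionary with unit columns and `H ≥ 0` sparse. The solver alternates
non-negative lasso coding (exact coordinate descent — with two atoms the
subproblem is tiny) and non-negative least-squares dictionary updates,
from a Macenko-style extreme-angle initialization, for at most 50
alternations or relative dictionary change < 1e-4; a zero-penalty
refit of the dictionary follows ("relaxed-lasso" style), because the
lasso's shrinkage otherwise biases the stain vectors enough to break the
idempotence of normalization. Concentration scales are the 99th
percentiles of the unpenalized coding — the same coding normalization
uses — so scale ratios are self-consistent. Pixels with OD norm < 0.15
are excluded from estimation (background); fewer than 100 tissue pixels
is an error naming the count. The hematoxylin column is identified by its
larger blue-channel component and stored first. The default sparsity
weight is 0.01 on the log10 OD scale.

No canonical target image exists for the method, so any fixed
`stain_profile` serves as the target; tests use the Ruifrok-style H&E
reference matrix.

## Object-level evaluation

Detection F1 uses the challenge rule: a predicted object is a true
positive iff its overlap exceeds **half the area of a ground-truth
object**, each ground-truth object claimable once; candidates are matched
greedily by decreasing overlap with ties broken by lower truth label then
lower prediction label, making results deterministic. Object Dice
averages per-object Dice over best-overlap partners, area-weighted, in
both directions. Object Hausdorff does the same with boundary-set
Hausdorff distances; objects with no overlap partner are paired with the
nearest object of the other map (smallest pairwise Hausdorff), and a map
with no objects at all contributes the image diagonal as a penalty. The
discrete boundary is fixed as pixels 4-adjacent to non-object so that the
brute-force oracle tests can demand exact (1e-9) agreement. Empty-vs-empty
scores Dice 1 and Hausdorff 0 (perfect agreement on emptiness).

## Morphometry conventions

The 13 features follow regionprops-style definitions with every ambiguity
pinned down:

* Moment ellipse axes use the pixel-as-unit-square (+1/12) correction, so
  a single pixel has positive axes; eccentricity is
  `sqrt(1 - (minor/major)^2)`; orientation is the major-axis angle CCW
  from the x-axis in `(-pi/2, pi/2]`.
* **Perimeter is the Crofton 4-direction estimate** (2×2 configuration
  counts with the integral-geometry LUT). The common weighted-border
  estimator overestimates circle perimeters by ~6 %, which would drag a
  disk's compactness to ~0.92; Crofton-4 is accurate to well under 1 % on
  disks, at the price of occasionally pushing `4πA/P²` marginally above
  1 — compactness is therefore clamped to 1 and documented as such.
* Convex area counts pixels whose centers lie in the closed convex hull
  of the object's pixel corners (never below the pixel count, exact for
  convex rasterized shapes); filled area uses per-component hole filling.
* Aggregation: sample (n−1) standard deviation; bias-uncorrected moment
  skewness; excess (Fisher) kurtosis; one gland or a zero-variance
  feature yields 0 for sd/skewness/kurtosis. Orientation is aggregated
  like any other feature because the method does so; its circular nature
  makes means near ±π/2 ill-behaved, which is flagged here rather than
  silently fixed.

The 78 patient columns are named `feature_statistic` in a fixed order
(`patient_feature_names()`).

## Survival modelling

The Cox partial likelihood with Efron tie handling is maximized by Newton
iterations with step-halving (the penalized log-likelihood never
decreases), converging at relative change < 1e-9 or 100 iterations, under
an L2 penalty `λ/2‖β‖²`. Features are z-scored inside the fit — required
for an isotropic penalty over columns whose raw scales span four orders
of magnitude — with the standardization stored and re-applied at
prediction; zero-variance columns get coefficient 0. Ridge (not lasso)
was chosen because the method calls only for "regularisation" and the
78-column, ~161-patient regime needs shrinkage, not selection; collinear
columns are kept. When a λ grid is supplied, each outer fold picks λ by
inner 3-fold concordance.

Harrell's C counts a pair as comparable when the shorter time carries an
event (at tied times, an event paired with a censored observation counts,
the event treated as earlier; two tied events do not), with ties in score
worth 1/2. Cross-validation uses seeded folds (resampled, still seeded,
if a training part would have fewer than 2 events), per-training-fold
standardization, and pools the out-of-fold risk scores; the median split
is taken on that pooled vector because a single threshold must cover all
patients, and whether the original analysis pooled out-of-fold or
refit-on-all scores is not stated. Scores exactly at the median go to the
low-risk group (documented tie rule). Kaplan–Meier curves and the
two-sample log-rank test delegate to the survival package's estimators
behind this package's interface; tests verify them against hand-computed
product-limit and O/E/V tables.

## The synthetic data and what it does (not) show

Gland images: each gland is a deformed ellipse — polar radius
`r(θ) = base·(1 + amplitude·s(θ))` with `s` a low-order random Fourier
series — with an optional concentric pale lumen, so the hematoxylin-dark
epithelium forms the ring-around-lumen structure contour-aware
segmentation targets. Two regimes mirror the benign/malignant contrast:
`regular` (semi-axis 10–16 px, aspect ≤ 1.5, amplitude 0.08, lumens in
90 %) and `deformed` (8–20 px, aspect ≤ 2.5, amplitude 0.35, lumens in
40 %). Touching pairs occur with regime probability; the ground truth
keeps them distinct. Colours come from a Beer–Lambert two-stain model
with smooth texture plus per-pixel granularity — the granular term leaves
some nearly pure-hematoxylin and pure-eosin pixels, as nuclei and
collagen do in real H&E, and without it two-stain factorization is
unidentifiable (any basis whose cone covers the two mixture directions
fits). Per-image stain perturbation (default 12 %) emulates lab-to-lab
variation.

Cohorts: each patient draws a gland count (negative binomial, mean 10)
and a deformed fraction (Beta(2,2)); every gland is rasterized and
measured with the package's own morphometry. Survival times are
inverse-transform samples from
`S(t|x) = exp(-(t/scale)^shape · exp(β'z))` with a Weibull baseline
(scale 60 months, shape 1.2 — a plausible colorectal-cancer survival
scale) and `z` the cohort-z-scored aggregate features named in
`true_beta`; censoring is independent exponential with its rate found by
bisection so the realized censored fraction hits the target (default
30 %). The default signal, `β = (1.25, −1.0)` on mean eccentricity and
mean solidity, was calibrated once so the true linear predictor's
concordance is ≈ 0.85, the stated study condition for the
cross-validation property; it was not revisited afterwards.

What passing tests show: the implementation is internally correct (exact
oracle agreement), the network can learn ring-shaped instances from
colour and shape cues, and the survival machinery recovers a known
morphology-driven hazard. What they do not show: performance on real
histology — the synthetic tissue has no nuclei texture, no scanner or
compression artifacts, no mucin or necrosis, colour classes far more
separable than real H&E, and gland-shape distributions that are invented
knobs rather than estimates of any real cohort.

## Known limitations

* The network is deliberately small and normalization-free; at full scale
  (width multiplier 1, 480-px crops) the same code runs but has not been
  exercised at that size on CPU.
* Non-overlapping tiling can in principle under-segment a gland whose two
  halves fail the seam-adjacency test; seam merging handles the common
  case (adjacent pixels across the seam) only.
* The Hausdorff pairing of unmatched objects follows the
  nearest-object convention; other implementations of the challenge
  metric may differ on degenerate inputs (empty maps), where this package
  fixes its own documented conventions.
* Orientation aggregation inherits the circular-mean problem noted above.
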