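---
title: "Automated suitable-cell selection: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated suitable-cell selection: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellcull)
```

## The problem

Nanocytology (partial wave spectroscopy, PWS) quantifies nanoscale
refractive-index fluctuations inside cells, and its signal is corrupted by
anything that is not a single, flat, clean cell. Before analysis, objects on
a smear slide therefore have to be triaged: *suitable* cells are isolated,
unfolded, debris-free and smooth-textured; everything else — debris-covered
cells, folded cells, overlapping clumps — is *unsuitable*. `cellcull`
automates this triage for slide-maps assembled from low-magnification
transmission tiles: segment candidate objects, quantify them with shape and
texture features, rank features with a nonparametric separability
criterion, and classify with an RBF-kernel support vector machine, with
ROC/AUC, sensitivity and bootstrap evaluation throughout.

Clump splitting is deliberately out of scope: a clump of cells is a single
unsuitable object, because nanocytology needs isolated cells, not cells
rescued from clusters.

## Image model and segmentation cascade

A slide-map is a gap-free, overlap-free row-major mosaic of tiles (default
tile 1024 × 1280 px). Illumination shading in transmission imaging is
multiplicative, so flat-field correction divides by a blank background image
and rescales to a constant level (`correct_illumination()`); background
pixels are clamped at 1/65535 of the dynamic range before division.
Grayscale is the unweighted mean of the three channels.

The detection cascade (`segment_slidemap()`) is, in order: flat-field
correction → grayscale → bicubic downsampling to half resolution
(Catmull-Rom kernel; output dimensions `ceiling(input/2)`) → H-minima and
H-maxima flattening → Sobel + Laplacian-of-Gaussian edge detection →
morphological cleanup (disk closing, hole filling, minimum-area pruning) →
nearest-neighbour upsampling of the mask to the full frame → connected-
component extraction with clockwise Moore boundary tracing. The cascade
contains no randomness.

Parameters with defaults (all in `seg_config()`):

* `h_minima_depth`, `h_maxima_depth` = 0.05 of the dynamic range. The exact
  flattening depth is a free parameter of the method; 0.05 suppresses
  within-cell texture while preserving the cell/background step, which in
  the synthetic model is ≈ 80 gray levels (0.3 of range). Both transforms
  are exact morphological reconstructions (hybrid raster/FIFO algorithm in
  compiled code), so a bump of depth *d* > *h* survives with depth exactly
  *d − h*.
* Sobel threshold: Otsu on the gradient-magnitude histogram. LoG scale
  `log_sigma` = 2 px, zero-crossings kept when the local response jump
  exceeds 0.75 of the mean absolute response.
* Edge maps are combined by union (`"or"`): either detector suffices, the
  inclusive reading of running both; `"and"` is available.
* `closing_radius` = 4 px at working resolution; `min_object_area` =
  400 full-resolution px², rescaled by the square of the downsampling
  factor; border-touching components are dropped by default because a
  partially imaged object cannot be verified whole.

## Feature bank

All gray-level features are computed over masked pixels only, on the 0–255
scale. The seven headline features:

* **Eccentricity** `sqrt(1 − b²/a²)` of the moment-equivalent ellipse
  (population second central moments of pixel centres). A printed form of
  this feature elsewhere is typographically ambiguous; the moment-ellipse
  definition used here is the standard one and is consistent with a
  roundish cell scoring ≈ 0.64.
* **Solidity** A/H with H the number of pixel centres inside or on the
  convex hull. Counting hull *pixels* (not the shoelace area of the
  centre polygon) is what makes a filled rectangle score exactly 1.
* **Normalized variance** σ²/μ² and **normalized kurtosis** E[(x−μ)⁴]/σ⁴
  (non-excess: a Gaussian scores 3), population moments of masked gray
  levels.
* **Entropy** −Σ p log₂ p over the 256-bin histogram; range [0, 8] bits.
* **Co-occurrence energy** Σ M²ᵢⱼ of the summed, mask-restricted gray-level
  co-occurrence matrix at offset 5 px in the eight compass directions,
  quantized to 64 levels (quantization depth is not dictated by the method;
  64 keeps the matrix well-populated on cell-sized crops).
* **Gabor response variance**: variance of the masked response to
  `exp(−(x²/σx² + y²/σy²)/2)·cos(2πu(x cosθ + y sinθ))`, averaged over
  θ ∈ {0°, 45°, 90°, 135°}; defaults σx = σy = 4 px, u = 0.1 cycles/px.
  The published form of this kernel is garbled in transcription; the
  kernel above is the standard Gabor form and we flag it as our
  interpretation. Pixels outside the mask are replaced by the masked mean
  before convolution so background content cannot leak in.

The full registry (~30 features) fills out the documented categories —
shape (area, perimeter, circularity, axis lengths, extent), histogram
moments and percentiles, per-channel colour means and ratios, co-occurrence
contrast/homogeneity/correlation, Gabor variance at u = 0.05 and 0.2,
gradient energy — plus two frankly non-canonical topology stand-ins (Euler
number, local-extrema density), since "topology" is undefined in the source
feature taxonomy. Only the seven headline features have authoritative
definitions; the rest are our documented choices.

## Nonparametric feature selection

For two classes, every sample `x_k` of class *i* is compared to an
inverse-distance-weighted mean of the reference class: weights
`w_l ∝ d(x_k, x_l)⁻¹` normalized to sum 1, with coincident points
tie-sharing the full mass (the limit of inverse-distance weighting). The
between-class scatter `S_b` accumulates outer products
`(x_k − M_j(x_k))(·)ᵀ` weighted by a per-sample scatter weight
`λ_k ∝ d(x_k, M_j(x_k))⁻¹` (normalized over the class), the class size and
the empirical prior; the within-class scatter `S_w` is the analogue with
the sample's own class as reference.

Three readings had to be fixed where the printed equations are ambiguous
or degenerate:

1. The weight normalizations run over the class actually being summed
   (reference class for `w`, own class for `λ`); the printed subscripts
   mix `n_i` and `n_j` inconsistently.
2. The within-class weighted mean **excludes the sample itself**. Composed
   with inverse-distance weights, the self-inclusive form puts all mass on
   the sample (distance zero), making `S_w ≡ 0` and the criterion
   undefined; self-exclusion is the only reading under which the
   within-class matrix is meaningful. Coincident *distinct* samples still
   tie-share.
3. The criterion is scalarized as `F = trace(S_w⁻¹ S_b)` (a determinant
   ratio is available via `method = "det"`). When `S_w` is poorly
   conditioned (duplicate or collinear features) a ridge
   `εI, ε = 1e-8·trace(S_w)/d` is added.

Features are z-scored before any distance computation (`standardize =
TRUE`): the criterion mixes features of wildly different units (pixels²,
bits, pure ratios) inside one Euclidean metric, and without standardization
the largest-scaled feature dominates every weight. Raw mode is available
for sensitivity checks.

Two properties worth knowing:

* **Invariance.** `F` is exactly invariant under *similarity* transforms
  (translations, rotations/reflections, uniform scaling) — the scatter
  pair transforms congruently and the inverse-distance weights are
  untouched. It is **not** invariant under general invertible linear maps:
  those change the metric, hence the weights (we measure relative shifts
  of a few percent). The trace-of-ratio form would be fully invariant only
  for the parametric scatter matrices, whose means are weight-free.
* **Non-monotonicity.** Adding a feature can *decrease* `F`, because the
  weights are recomputed in the larger subspace. An exact duplicate of a
  selected feature leaves `F` unchanged (the ridge neutralizes the
  redundant direction); it can therefore still outscore a feature whose
  addition lowers `F`.

The search (`stepwise_select()`) is sequential floating forward selection:
add the best feature, then while removing some single feature (other than
the newcomer) strictly improves on the best criterion seen at that smaller
subset size, remove the best such feature. The size-indexed guard is what
guarantees termination. Ties break by column order; the search is fully
deterministic. Degenerate candidate subsets (within-class scatter
numerically zero, e.g. a feature constant on every object) score 0 rather
than aborting the search.

## Classification and evaluation

The suitability classifier is an SVM (via `e1071`/libsvm) with linear,
polynomial or Gaussian RBF kernel `exp(−‖u−v‖²/2σ²)`. Penalty and scale
are tuned by stratified 10-fold cross-validation over log grids
`C ∈ 2^{−5,…,15}` and `γ = 1/(2σ²) ∈ 2^{−15,…,3}` (step 2); fold
assignment is deterministic in the seed and audited (`model$cv$fold_ids`).
The source text uses 10-fold tuning for the main classifier but 4-fold in
its kernel comparison; both are a `folds` argument away, and we default to
10. Baselines: kNN with k = 3 (scores are suitable-vote fractions) and
random forest with 500 trees, `mtry = round(sqrt(p))`. Standardization
parameters are frozen at training time, so test-set leakage is
structurally impossible.

Evaluation: error rate (misclassified/total), sensitivity = suitable-cell
recall (the positive class is `suitable`, switchable), threshold-sweep ROC
anchored at (0,0) and (1,1), trapezoid AUC (equal to pairwise concordance
with ties counted ½), and stratified bootstrap percentile intervals
(default B = 1000, 5th/95th percentiles; resampling within class so no
resample loses a class). The overtraining audit (`feature_count_sweep()`)
retrains at k = 1…7 features, records training/test/LOOCV error, and tests
the gap sequence for an increasing trend with Kendall's tau (one-sided
p < 0.05 flags overtraining); "systematic increase" has no published
operationalization, so the tau test is our rule.

## The synthetic generator

No image data accompanies the method, so the package ships a seeded
generator (`scene_spec()`, `generate_slide_scene()`, `render_cell()`) that
emulates what the method needs and nothing more: stained elliptical cells
darker than a bright background (8-bit, background 220, stain RGB
(150, 110, 160) — transmission polarity and bit depth are our recorded
conventions), three unsuitable phenotypes (debris speckle, fold crease +
edge concavity, two-lobed overlaps with darker intersections), smooth
vs coarse texture (sd 3 vs 15 gray levels), a multiplicative quadratic
illumination gradient (amplitude 0.3 of the background level), and mild
sensor noise (sd 1). Cell radii are 30–60 px, the scale of buccal squamous
cells under a 10× objective. Placement is rejection sampling on bounding
circles, capped at 1000 attempts per object, so all ground-truth objects
are pairwise disjoint. One master seed drives per-object sub-streams, so
scenes are byte-identical given the seed and object renders do not depend
on placement order.

What the generator does *not* emulate: Papanicolaou stain chromatics,
optical point-spread, depth-of-field, 3-D cell structure, slide-edge
artifacts, or density-dependent clumping beyond the explicit overlapping
phenotype. Passing the synthetic benchmark therefore demonstrates that the
pipeline's machinery is correct and that the features separate the planted
phenotype contrast; it does not certify performance on real smears, whose
suitable/unsuitable contrast is weaker and messier than the planted one.

`generate_feature_dataset()` plants a known signal directly in feature
space (two classes, informative features shifted by a chosen number of
standard deviations) and is the test harness for the selection and
classification stages.

## The benchmark and problem sizes

`run_benchmark()` reproduces the full experiment at its published scale:
1000 training and 360 testing objects, half suitable in each set,
7 selected features, RBF-SVM tuned by 10-fold CV. The default (acceptance)
mode renders objects straight from ground truth, which isolates the
feature/selection/classification chain from segmentation noise; a
`mode = "scene"` variant runs the full image pipeline and labels segmented
objects by best-IoU match against ground truth. Segmentation itself is
exercised on a 2 × 2-tile scene (tiles 1024 × 1280) with 20 planted
objects. These sizes are the package's test conditions; unit tests use
smaller scenes and tables so the suite stays quick.

A note on the shuffled-label negative control
(`run_benchmark(shuffle_labels = TRUE)`): the permutation distribution of
the control AUC is symmetric about 0.5 (complementary permutations
produce exactly negated SVM scores and identical feature selections) but
it is *not* tight. The true classes remain two well-separated clusters in
feature space whatever the labels, so any residual alignment between a
permutation-trained decision function and the cluster axis separates the
test classes with a random sign; cross-validated re-tuning on the
permuted labels damps this (it prefers heavily regularized, nearly flat
score surfaces), leaving most control runs near 0.5 with occasional
excursions. If the hyperparameters are instead frozen at the real model's
values the control AUC becomes almost Bernoulli on {0, 1} — a vivid
reminder that chance-level *expectation* does not mean chance-level
*realizations* when the features are this separable. The control is run
with full re-tuning for exactly this reason.

## Known limitations

* The nonparametric criterion is O(n²) in samples per evaluation and the
  floating search evaluates many subsets; for feature banks far beyond
  ~100 features or samples beyond ~10⁴ a cheaper pre-filter would be
  needed.
* Only two-class problems are supported, matching the task.
* The 93 unnamed features of the source taxonomy are represented by
  documented stand-ins; results attached to individual registry features
  (other than the headline seven) are not comparable across
  implementations.
* Boundary tracing assumes 8-connected components; one-pixel-wide
  appendages are traced but their shoelace area underestimates pixel
  count, which is why the area check tolerates 10% on small disks.
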