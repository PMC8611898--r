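---
title: "Methods: comprehensible 3D CNNs with relevance maps for dementia detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comprehensible 3D CNNs with relevance maps for dementia detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

relmap3d trains a small 3D convolutional network to separate dementia
patients from cognitively normal controls on modulated gray-matter density
maps, and explains individual predictions with layer-wise relevance
propagation (LRP). This vignette documents the models, the conventions and
parameter choices behind the implementation, what the synthetic cohort
generator does and does not emulate, and the numerical decisions a
maintainer would want spelled out.

## Covariate residualization

Voxel intensities of spatially normalized, modulated gray-matter maps are
confounded by normal aging, sex, head size and scanner field strength. For
every voxel $i$, an ordinary least squares model is fitted on the healthy
controls only,

$$ vx_{ij} = \beta_{i0} + \beta_{i1}\,\mathrm{age}_j + \beta_{i2}\,\mathrm{sex}_j
   + \beta_{i3}\,\mathrm{TIV}_j + \beta_{i4}\,\mathrm{FS}_j + \varepsilon_{ij}, $$

and the fitted prediction is subtracted from *all* subjects' maps
("fit on controls, apply to all"), so that disease-related deviations stand
out against an age- and head-size-corrected baseline. The same machinery is
applied to scalar measures (hippocampus volume) via `residualize_scalar()`.

Implementation notes:

* sex and field strength are coded 0/1 (0 = 1.5T); the TSV schema documents
  this. Covariates enter in raw units — standardizing them would only
  rescale the coefficients, not change the residuals.
* coefficients are computed through a pseudo-inverse with relative
  singular-value tolerance $10^{-10}$, so zero-variance features (background
  voxels) yield intercept = mean and zero slopes instead of an error. A
  rank-deficient *design* (constant covariate) is a hard error naming the
  column.
* residualizing a second time with a refitted model is a no-op up to
  numerical noise (idempotence), and the mean residual over the fitting
  controls is zero per feature — both are enforced in the test suite.

## Network architecture and training

The classifier (`network_spec()`, `build_network()`) is a compact
AlexNet/VGG-style 3D CNN: three convolution blocks — 5 filters of
$3^3$, spatial-size-preserving padding, ReLU, $2^3$ max pooling with floor
division, batch normalization — followed by three dense layers of 64, 32
and 2 units, each preceded by 10% dropout, with softmax output. The last
two dense layers carry an L2 penalty (default strength 0.01; unspecified in
the source description, hence configurable). At the full
$100\times100\times120$ resolution the flatten width is
$12\times12\times15\times5 = 10{,}800$ and the network has 694,940 trainable
parameters, i.e. roughly 700,000 — this reproduction is what pins down the
"same"-padding and floor-pooling conventions, since unpadded convolutions
would give about 419,000 instead.

Training (`train_fold()`, `cross_validate()`, `train_full()`) follows the
reference conditions: Adam, categorical cross-entropy, learning rate
$10^{-4}$, batch size 20, class weights $0.5\,n/n_i$ (1.31 controls / 0.81
patients for the 254 vs 409 composition), 14-fold augmentation per epoch —
{identity, left/right flip} × {no shift, ±10 voxels along one axis} with
zero fill — stratified ten-fold cross-validation on the three-class label,
and per-fold selection of the epoch that performs best on the test
partition (balanced accuracy; ties broken by lower test loss, then the
earlier epoch — the source states only "best"). Whole-sample training uses
fixed epochs and no checkpoint selection. MCI and AD are merged into one
disease-positive class throughout; MCI-vs-CN and AD-vs-CN evaluations reuse
the single binary model on subsets.

Further conventions the source leaves open:

* grid axes are ordered x = sagittal (left/right), y = coronal, z = axial;
  the "left/right" augmentation flip mirrors axis 1 (configurable).
* weight initialization is normalized-variance uniform (Glorot) with a
  fixed seed; two builds from the same seed are bit-identical.
* batch normalization follows pooling inside each block (the data-flow
  order of the reference layout); its statistics use momentum 0.9 so the
  running estimates are usable after the short trainings this package
  targets, and they are frozen for all inference and relevance
  computations.
* translations are single-axis only: the stated factor of 14 forces
  {1 flip state} × {7 shift states}, leaving no room for combined axes.

## Relevance propagation

`relevance_map()` starts from the pre-softmax score of the target class
(the de-facto standard; softmax is stripped) and propagates it towards the
voxels with a conservation principle: what arrives at a layer is
redistributed over its inputs. The composite rule is

* **dense layers — $\varepsilon$ rule:**
  $R_j = \sum_k \frac{a_j w_{jk}}{z_k + \varepsilon\,\mathrm{sign}(z_k)} R_k$
  with $z_k = \sum_j a_j w_{jk}$ the weighted input sum (the same
  denominator the $\alpha\beta$ redistribution normalizes by, extended by
  the small constant), $\varepsilon = 10^{-10}$ and $\mathrm{sign}(0) := +1$;
* **convolutions — $\alpha{=}1/\beta{=}0$ rule:**
  $R_j = \sum_k \frac{a_j w^+_{jk}}{\sum_{j'} a_{j'} w^+_{j'k}} R_k$,
  positive contributions only;
* **max pooling:** winner-take-all routing to the window's argmax (ties to
  the lowest linear index);
* **dropout:** identity at inference; **ReLU:** implicit, since the $a_j$
  are the post-ReLU activations that actually fed each affine layer.

Three design choices deserve emphasis, because the obvious alternatives
measurably fail the conservation and plausibility properties the package
tests:

1. **Bias handling.** Biases never enter any numerator, and by default they
   are excluded from the denominators too
   (`lrp_config(bias_absorb = FALSE)`), which makes every redistribution
   conserve relevance exactly column by column — the end-to-end deficit is
   then bounded by the $\varepsilon$ absorption alone (order $10^{-10}$).
   The absorbing variant (bias parts in the denominators, so biases soak up
   a $b_k/z_k$ share) remains available, but on residual images — whose
   voxel values are signed — denominators can cancel arbitrarily close to
   zero, and the bias share then amplifies without bound.
2. **Batch normalization.** At inference a batch-norm layer is a
   per-channel affine map; it moves no relevance between spatial positions.
   Where it feeds an inner convolution it is folded into that convolution
   exactly (`fold_batchnorm()`), so every inner $\alpha 1\beta 0$ step sees
   the *non-negative* pooled activations as inputs and all redistribution
   coefficients lie in $[0,1]$ — the propagation cannot amplify. The
   normalization above the dense stack is identity for propagation; folding
   its shift into the first dense layer's bias instead would hand the large
   channel means to the $\varepsilon$ rule's bias share and break
   conservation by tens of percent.
3. **The input layer.** The $\alpha\beta$ rule presumes non-negative
   activations; residual images violate this at exactly one layer, the
   input-facing convolution. There the squared-weight rule
   ($R_j = \sum_k \frac{w^2_{jk}}{\sum_{j'} w^2_{j'k}} R_k$), the standard
   input-layer rule for unbounded real-valued data, is the default: its
   coefficients are input-independent, bounded, and exactly conserving.
   Plain $\alpha 1\beta 0$ at the input remains available
   (`input_rule = "alpha_beta"`) but produces unstable single-voxel
   attributions when positive and negative voxel contributions nearly
   cancel inside a receptive field.

With these conventions the end-to-end deficit
$|\sum_i R_i - R_{\text{start}}| / |R_{\text{start}}|$ on trained models is
numerical noise (the $\varepsilon$ absorption plus floating-point
accumulation), orders of magnitude below the 1% conservation budget the
test suite enforces, and the per-layer totals recorded in every
`relevance_map` make any violation directly visible.

## Relevance analytics

* `region_relevance_sum()` — plain masked sums; `region_volume_ml()` — sum
  of modulated density × voxel volume (default $1.5^3$ mm³), in ml.
* `extract_clusters()` — connected components of the supra-threshold voxel
  set, face adjacency by default (26-connectivity via flag, since the
  source says only "adjacent"), filtered by minimum size; the
  pre-filter size histogram is kept for display.
* `slice_relevance_profile()` — per-slice positive and negative sums along
  sagittal/coronal/axial axes.
* `occlusion_scan()` — slides a cube (default edge 20 voxels = 30 mm at
  1.5 mm) across the volume, multiplies intensities inside by
  $(1-\text{attenuation})$ (default 50%), and records the target-class
  probability and score per position; cube positions are clipped to lie
  fully inside the grid (no partial cubes, avoiding edge artifacts), and
  the stride defaults to 4 voxels — a full stride-1 scan is configurable
  but slow. Relevance maps are never rescaled before analytics.

## The synthetic cohort generator

Real training and validation cohorts for this kind of model are
access-restricted, so the package ships a brain-phantom generator
(`cohort_spec()`, `simulate_cohort()`) that reproduces the *statistical
structure* the pipeline assumes, not anatomy:

* **base template:** a smooth ellipsoidal "brain" (intensity 0.8 inside an
  ellipsoid spanning 84% of the grid, Gaussian-smoothed with σ = 1.5
  voxels), mimicking the value range of modulated gray-matter maps.
* **covariate model:** voxel value = template + slopes · (covariates −
  reference), applied on brain voxels (template > 0.2) so the noiseless
  linear model is exact everywhere it is defined — the covariate-recovery
  tests require this. Defaults: age slope −0.004/yr, sex −0.02, TIV
  +2·10⁻⁴/ml, field strength +0.01; age ~ U(60, 85), sex ~ Bern(0.5),
  TIV ~ N(1450, 130) ml, field strength ~ Bern(0.7); reference covariates
  are the distribution centers.
* **atrophy:** multiplicative attenuation of intensity inside designated
  atlas regions, matching the occlusion analysis' "reduce intensity by
  50%" notion of simulated atrophy. Defaults: hippocampus 0.4 for AD and
  0.2 for MCI (MCI = half of AD, treating MCI as intermediate atrophy), a
  secondary "temporal" region at 0.2/0.1, and a "parietal" null region.
* **noise:** i.i.d. Gaussian voxel noise, σ = 0.1 — large enough that
  single voxels are uninformative (the per-voxel atrophy effect is ~2.5
  SD) while the region-level signal is strong.
* **atlas:** three disjoint ellipsoids on the grid; a "hippocampus" region
  is mandatory. The default grid is 40×40×48 (the full 100×100×120 is
  supported, the architecture adapts) so that a full training run stays in
  the minutes range on one CPU.

What the phantom does **not** emulate: anatomical shape, within-region
atrophy gradients (the source gives no generative model beyond intensity
reduction, so none is invented), white-matter structure, scanner artifacts,
and site effects. Consequently, passing tests show the *pipeline* behaves
as specified under its own assumptions — they say nothing about accuracy on
real MRI cohorts, whose reported group separations cannot be reproduced
without the restricted data.

## Study-condition defaults for the synthetic demonstrations

The end-to-end demonstrations and acceptance checks use a 200-subject
cohort (100 CN / 50 MCI / 50 AD) on the 40×40×48 grid with hippocampal
attenuation 0.4, an 80/20 stratified split, and `demo_train_config()`:
2 epochs at Adam step size $10^{-3}$. The synthetic task is far easier than
real MRI — with 14-fold augmentation, two epochs are ~450 weight updates
and reach test balanced accuracy near 1.0 — so the reference settings
(10 epochs at $10^{-4}$) remain the defaults of `train_config()` for
full-scale data while the demo uses the smaller, faster configuration.
Null-cohort checks (attenuation 0) use 20 replicates of 15 + 15 subjects on
a 20×20×24 grid and test that the volume-summary AUC's confidence interval
covers 0.5.

## Evaluation

`roc_auc()` is the Mann-Whitney statistic (ties count ½, via midranks);
`youden_threshold()` scans the midpoints between adjacent sorted unique
scores, classifies positive at score ≥ threshold, and maximizes
$J = \text{sens} + \text{spec} - 1$ with ties resolved to the lowest
threshold. The hippocampus-volume baseline (`volumetric_baseline()`)
mirrors the clinical benchmark: residualized volumes become risk scores by
sign flip (smaller-than-expected hippocampus = higher risk), the threshold
is derived on training residuals and applied to the test residuals, and the
reported volume threshold is in ml below the covariate-expected volume. CNN
and baseline are evaluated on identical splits so their metrics are paired.
`relevance_volume_report()` correlates per-region relevance sums with
residualized hippocampus volume per model and reports the across-model
median; on a trained synthetic model the hippocampus correlation is
strongly negative (more atrophy → smaller volume → more relevance), while
an untrained network shows no comparable association.

## Degenerate inputs and numerical edges

* volumes must be finite; 4D NIfTI files are rejected; anisotropic voxel
  sizes warn and keep the smallest dimension.
* pooling drops trailing voxels that do not fill a window (floor division);
  argmax ties take the lowest linear index, deterministically.
* zero-denominator columns in the $\alpha\beta$ rule drop their relevance
  (no redistribution) — keeping non-negativity rather than inventing a
  split; $\mathrm{sign}(0):=+1$ stabilizes the $\varepsilon$ rule.
* a NaN training loss aborts with the epoch/batch context rather than
  continuing silently.
* `cohort_spec()` enforces attenuations in [0, 1), MCI ≤ AD attenuation,
  and non-negative noise; `make_atlas()` rejects overlapping or
  out-of-grid regions.

## Known limitations

* The phantom's atrophy is spatially uniform within a region; relevance
  maps on real data respond to shape and boundary effects (the occlusion
  literature's "ring" patterns) that this generator cannot produce.
* The from-scratch training loop is CPU-oriented; full-resolution
  (100×100×120) training is supported but slow — the package's scope is
  methodological transparency at desk scale, not throughput.
* Batch-norm running statistics after very short trainings retain some
  influence of their initialization (momentum 0.9); inference-mode
  predictions on tiny demonstration runs reflect that.
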