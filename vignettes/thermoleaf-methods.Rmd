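---
title: "Methods: from leaf thermal images to a drought classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from leaf thermal images to a drought classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermoleaf)
```

## The problem

When a plant closes its stomata under water limitation, transpiration —
and with it evaporative cooling — drops, and the leaf warms relative to a
well-watered control. Handheld radiometric thermal cameras make that
signal accessible at the single-leaf scale: an image of a leaf held
against a paper backdrop is a grid of surface temperatures in °C. The
bottleneck is post-processing: isolating the leaf pixels from the
backdrop, summarizing them robustly, and deciding whether a leaf belongs
to a well-watered (WW) or a dry-down (DD, irrigation withheld) plant.

thermoleaf implements that pipeline end to end: spectral high-pass
filtering, gradient-based leaf-mask segmentation, robust thermal feature
extraction, Kolmogorov–Smirnov feature screening, and two classification
pipelines (random forest and single-hidden-layer perceptron) with
stratified splitting, standardization, mutual-information feature
selection and seeded random-search tuning.

## Segmentation model and assumptions

The segmentation chain is fully non-parametric — every threshold is
derived from the image at hand — and label-blind.

1. **High-pass filter.** The 2-D FFT of the frame is computed and every
   Fourier coefficient whose magnitude is at least the DC (zero-frequency)
   magnitude is zeroed; the real part of the inverse transform is the
   filtered image. In natural thermal images the DC term dominates, so in
   practice this subtracts the flat backdrop level. Two degenerate cases
   are handled explicitly: if the DC magnitude is already numerically zero
   (a re-filtered image) only DC itself is removed, which makes the filter
   idempotent; and a constant frame maps to zero.
2. **Gradient magnitude.** Sobel 3×3 by default (central differences
   selectable), with edge replication at the border so flat frames have
   identically zero gradient. The magnitude convention makes the result
   non-negative, translation-invariant and positively homogeneous.
3. **Quartile-fence binarization.** The first and third quartiles (q1, q3;
   linear interpolation, type 7) of all gradient values give
   IQR = q3 − q1 and the Tukey fences thr_dw = q1 − 1.5·IQR,
   thr_up = q3 + 1.5·IQR. The default (`two_sided`) mask turns a pixel on
   when its gradient is outside the fences. Because gradient magnitudes
   are non-negative while thr_dw is usually negative, a lower-only test is
   vacuous on real inputs; a `low_only` mode is provided for comparison,
   but only the two-sided rule can produce usable outline masks. The
   assumption behind the fences is that gradient magnitudes are mostly
   small and homogeneous (backdrop, leaf interior) except along the leaf
   outline, which shows up as upper outliers.
4. **Morphological refinement.** Dilation with a disc of radius 3 px
   closes gaps in the outline ring, flood-fill hole filling recovers the
   leaf interior, erosion restores the boundary, and connected-component
   labeling (8-connectivity; ties broken toward the first label in scan
   order) keeps the largest blob. A `min_area` floor of 50 px rejects
   noise specks that would otherwise win largest-component selection on
   degenerate inputs, and an all-on mask is treated as a failure.

### Numerical choices in segmentation

Two defaults deserve explanation because they were genuinely open:

* **Erosion element one pixel larger than the dilation element.** The
  fence-binarized gradient ring straddles the true edge (a step edge
  excites the 3×3 derivative kernel one pixel on each side), so the filled
  ring's interior systematically overshoots the leaf by about one pixel
  all around. A symmetric closing preserves that bias; eroding with a disc
  of radius `struct_radius + 1` re-centers the recovered boundary on the
  true one. `erode_radius = struct_radius` restores the symmetric
  behavior.
* **Relative numerical floor on the gradient (1e-9 × max).** On noiseless
  or near-noiseless frames the inverse FFT leaves round-off residue of
  order 1e-15 across the whole image; without a floor the quartile fences
  would chase that residue rather than real structure. The floor is
  relative, so it never affects images with genuine content.

Quantiles use type-7 (linear) interpolation everywhere — fences,
features, physiology flags — so every threshold in the package is
reproducible from one stated convention.

## Thermal features

Temperatures under the mask are first passed once through the same
1.5·IQR fence (values strictly outside are dropped; with IQR = 0 equal
values are retained), then nine indicators are computed: mean, standard
deviation (sample, n−1, by default; population selectable), median, 25th
and 75th percentiles, IQR, max, min, and range. The single-pass fence is
what makes the features robust to small mask misalignments: a thin ring
of backdrop pixels leaking into the mask is fenced out as long as it
remains a minority. This robustness is *effective*, not bitwise — the
fence is re-estimated on the contaminated sample, so which extreme leaf
pixels get clipped can shift slightly. The test suite operationalizes the
property as: under a 1-px mask dilation at 5 °C contrast, location
indicators move by less than 1% of the contrast and every indicator by
less than 10%, against a ~100% movement of the minimum without the
filter.

A floor of 10 usable pixels (configurable) guards the indicators against
meaningless tiny regions.

## Feature screening

Each feature is compared between the WW and DD groups with a two-sample,
two-sided Kolmogorov–Smirnov test (asymptotic p-values); features with
p < α (default 0.05) are kept. Screening runs on the full labeled table
before the train/validation split by default — replicating the order in
which feature removal precedes the split — with `after_split_idx` as the
leakage-free alternative. No multiple-testing correction is applied,
deliberately: the screen is a coarse filter ahead of the classifiers, not
an inferential endpoint.

## Classification pipelines

* **Split.** Stratified by class, |T| = ⌊0.75·N⌋; with a 419-sample
  balanced cohort this is 314 training / 105 validation.
* **Standardization.** Per-feature (x − mean)/sd with parameters fitted on
  training rows only; zero-variance columns pass through centered with a
  warning.
* **Feature selection.** The top-K features by estimated mutual
  information with the label. The estimator is a plug-in on equal-frequency
  bins (at most 10) of each feature against the binary label, with a tiny
  seeded jitter (1e-10 relative) so heavily tied data still rank
  deterministically. K defaults to 3 for the random forest and 7 for the
  perceptron.
* **Tuning.** Random search (default 25 draws) over a documented grid —
  RF: max depth {3, 5, 7, 10} (enforced through a maximum of 2^depth
  terminal nodes), minimum samples per leaf {2, 5, 10}, trees {100, 300},
  K {3, 5, 7, 9}; MLP: hidden size {25, 50, 100}, L2 decay {1e-4, 1e-3},
  K {3, 5, 7, 9} — scored by stratified k-fold cross-validation (k = 10)
  on the training subset. Within each fold, scaling and selection are
  refitted on the fold's training rows, so CV scores are leakage-free.
  The best configuration is refit on the full training subset.
* **Evaluation.** 2×2 confusion matrix (rows true, DD first), per-class
  precision/recall/F1/support, overall accuracy. F1 is 2PR/(P+R), defined
  as 0 at P+R = 0. The per-class "weighted accuracy" column sometimes seen
  in report tables has no standard definition and is not emitted.

The perceptron is `nnet`'s single-hidden-layer network: hidden size 50 by
default, L2 weight decay, at most 500 iterations, no adaptive
learning-rate scheduling (nnet optimizes by BFGS rather than a stochastic
gradient method; hidden size, decay and iteration budget are the knobs
that correspond across implementations). The random forest grows 100
trees by default — a conventional choice, configurable.

## The synthetic scene generator

No public leaf-image corpus accompanies this problem, so the package
ships a generator that gives every stage a ground truth. A scene is a
leaf-shaped region (ellipse, or unions of rotated ellipses labeled
"lobed"/"okra" that exercise mask concavities without claiming botanical
fidelity) on a uniform paper backdrop at 22 °C. Leaf pixels are
`leaf_temp_mean` plus a smooth diagonal ramp of amplitude `leaf_temp_sd`
plus iid jitter of the same sd; the frame is Gaussian-blurred
(`blur_sigma`, default 1 px, for optics) and perturbed with iid sensor
noise (`noise_sd`, default 0.2 °C). The truth mask records the pre-blur
support. Scenes are pure functions of their spec, including the seed.

Cohorts draw per-sample leaf temperature (between-sample sd 0.8 °C,
mimicking genotype diversity), size, rotation and geometry, with DD
leaves offset +2 °C above WW by default — the direction follows from
stomatal closure suppressing evaporative cooling; the magnitude is a
moderate, realistic leaf-warming effect for progressive drought, chosen
once and used as the study condition throughout the tests. Default frames
are 96×128 px, a 4:3 aspect matching thermal-camera output at a size that
keeps the simulation-heavy test suite fast; the pipeline itself is
resolution-independent and parses full 640×480 exports.

What the generator does **not** emulate: leaf venation and within-leaf
thermal texture, petioles, specular backdrop artifacts, emissivity
variation, camera fixed-pattern noise, or multi-leaf scenes. Passing
tests therefore demonstrate algorithmic correctness and statistical
behavior under controlled contamination, not field performance on real
imagery.

## Physiological cross-check

Predictions can be joined with per-sample physiology (volumetric soil
water content %, PSII efficiency, leaf water potential). A sample is
flagged when a trait falls outside the 1.5·IQR fences of its *own
treatment group* — the same robust device used everywhere else. The
output tags each validation sample `DD_DD`, `DD_WW`, `WW_DD` or `WW_WW`
(true, then predicted) and reports flag rates by tag and by correctness.
The claim is associational only: misclassified leaves tend to be the ones
whose physiology was anomalous for their label (e.g. a dry-down pot that
never dried), which is a consistency check on the classifier, not a
causal statement.

## Problem sizes and determinism

The test suite and the acceptance script size their simulations to run
comfortably on one CPU: 20 seeded scenes for segmentation recovery, 1,000
repetitions at n = 200/group for KS null calibration, and 100
scenes/class for the end-to-end classification runs, with 25 random-search
draws per model. Every stochastic stage (split, folding, search, model
fits, jitter) derives its seed from one global seed, and a repeated run
with the same seed is bit-identical — this is asserted in the tests.

## Known limitations

* The fence-based mask assumes one dominant leaf against a homogeneous
  backdrop; cluttered scenes or multiple leaves violate it (the largest
  component wins, the rest is discarded).
* Asymptotic KS p-values are slightly conservative at moderate n; the
  exact method is available for small samples.
* The binned MI estimator is a ranking device, not an unbiased MI
  estimate; only the induced order matters here.
* Screening before the split leaks label information into feature
  choice. It is the default for fidelity to the pipeline order it
  reproduces; the leakage-free variant is one argument away.
* With heavy class imbalance the stratified splitter errors rather than
  silently producing single-class sides.
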