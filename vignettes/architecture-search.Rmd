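---
title: "Designing compact lesion-classification CNNs by Bayesian optimisation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing compact lesion-classification CNNs by Bayesian optimisation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(echonet)
```

## The problem

Benign and malignant breast lesions differ in ultrasound B-mode images
through a handful of gross features a radiologist reads routinely: the
regularity of the lesion boundary, the echogenicity of its interior
relative to the surrounding tissue, and the acoustic behaviour of the
band *posterior* to the lesion (enhancement behind fluid-filled cysts,
shadowing behind attenuating solid masses).  echonet implements an
automatic way of designing a small convolutional network for this binary
decision: instead of transferring an ImageNet-scale architecture, a
three-block backbone family is searched over five hyperparameters with
Bayesian optimisation, and the resulting compact model is evaluated with
stratified cross-validation and audited with saliency maps.

## The backbone family and the kernel rule

Every member of the family has the same skeleton on a 128×128 grayscale
input: three blocks, block *i* repeating (3×3 convolution → batch
normalization → ReLU) *B* times, a 2×2 stride-2 max-pool after blocks 1
and 2, then global average pooling, a two-unit fully connected layer and
softmax.  The searched setting is

* `B` — convolutional layers per block, 1–5 (architectural depth);
* `Opt` — solver: Adam, SGD with momentum, or RMSProp;
* `Lr` — L2-regularization coefficient, `1e-10`–`1e-2` (log scale);
* `Mn` — mini-batch size, 32/64/128;
* `Epo` — maximum epochs, 50–250.

The first block uses `numKernal = 128 / sqrt(B)` kernels, rounded half
away from zero, and the count doubles per block.  The divisor keeps the
parameter budget roughly flat as the depth grows:

```{r kernels}
sapply(1:5, kernelCount)
```

Two written conventions in the method's description are mutually
inconsistent, and the implementation resolves them explicitly rather
than silently:

* **"depth" in the kernel rule.**  Read literally as the fixed block
  count 3, the rule would give the same width for every `B` and could
  not produce the 364 final-layer feature maps that the optimal `B = 2`
  configuration is reported to have.  Binding depth to `B` gives
  91 → 182 → 364, which is the only consistent reading; the builder uses
  it.
* **Convolution stride.**  A stride of 2 is stated for the
  convolutions, but up to 15 stride-2 convolutions plus two pools
  starting from 128 pixels collapse the spatial extent below 1×1 — the
  deeper half of the search space would be unrealizable.  Convolutions
  therefore run with stride 1 and padding 1, leaving all spatial
  reduction to the pools; the map before global average pooling is a
  quarter of the input side for every `B`.

Training constants are fixed at their stated values: initial learning
rate `1e-4`, momentum 0.9, max-pooling stride 2.  `trainModel()` exposes
the learning rate for degenerate-case tests, but the default is never
changed by the package itself.

The reported optimum, `optimalHyperParams()` (`B = 2`, Adam,
`Lr = 6.8012e-7`, `Mn = 64`, `Epo = 50`), builds the 6-conv-layer
network:

```{r optimal}
spec <- buildArchitecture(optimalHyperParams())
c(convLayers = nConvLayers(spec), finalMaps = finalBlockKernels(spec))
```

## The search

The objective `f(hp)` is the classification error of the backbone
trained under `hp`, measured on held-out examples.  The method's own
description states the validation split in one place and the test split
of the first partition in another; `echonet` takes the held-out set the
caller's objective closure defines, and the pipeline uses a validation
split by default.  The loop (`runSearch()`) is conventional Bayesian
optimisation:

1. evaluate 4 random settings (log-uniform in `Lr`, uniform elsewhere);
2. fit a Gaussian-process surrogate to all observations;
3. pick the candidate maximising expected improvement over the best
   observed error;
4. evaluate it, append, repeat until 50 evaluations;
5. return the setting with the lowest observed error.

Settings are encoded into `[0, 1]^7`: one-hot solver, scaled
`log10(Lr)`, scaled batch-size index, scaled `B`, scaled `Epo`.  The
surrogate uses a Matérn 5/2 kernel with per-dimension (ARD)
lengthscales, fitted by marginal likelihood (`optim`, L-BFGS-B, warm
started between refits), with a fixed noise of `1e-6` on standardised
targets acting as jitter — enough for the posterior mean to interpolate
noise-free observations and to survive duplicated settings.  The
acquisition is maximised over a seeded pool of 2048 random candidates
rather than by gradient ascent; the space is seven-dimensional and
partly discrete, where a dense random pool is simpler and adequate.
Ties in expected improvement are broken by a seeded draw.  A
non-finite objective value is recorded as a failure observation at
error 1.0 with a warning, so a crashed training run cannot halt the
search.

These are deliberate choices on points the method statement leaves
open: the GP kernel family, the categorical encoding, and the
acquisition maximiser are all unspecified there.

## Regions of interest and augmentation

Annotations are ordered boundary points.  `boundingRect()` takes the
axis-aligned bounding box (the stated "minimum-area rectangle" is
interpreted as axis-aligned — the same object is also called a
rectangular bounding box, and rotated rectangles would not compose with
axis-aligned cropping); `expandRect()` adds the 8% margin split
symmetrically, 4% per side, rounded outward and clamped to the image;
`cropResize()` resamples with separable bicubic interpolation using the
Catmull-Rom kernel (`a = -0.5`), pixel-centre aligned, edge-replicated,
with the output clipped to the intensity range of the crop so
interpolation overshoot cannot leave the input range.

Each training RoI contributes exactly four derived images
(`augmentRoi()`): a vertical-axis mirror and three truncated-SVD
reconstructions retaining 25%, 35% and 45% of the singular values.  The
ratio is read as a fraction of the *count* of retained singular values,
`k = max(1, round(ratio * min(h, w)))` — matching the phrase "selected
top singular values" — not of their energy; an energy-based reading
would keep far fewer components on speckle-like spectra.
Reconstructions are clipped to `[0, 1]`, not renormalized, so intensity
calibration survives.  Augmentation happens strictly after the
cross-validation split and only on training/validation members; the
pooling helper records per-image provenance so the leakage guard is a
direct set assertion.

## Evaluation

`stratifiedFolds()` partitions each class separately (remainders to the
earliest folds, so per-class test counts differ by at most one), and
carves a stratified 10% of the non-test examples out as validation.
Metrics follow clinical convention with malignant as the positive
class: sensitivity is malignant recall, specificity benign recall.  The
best fold maximises accuracy with ties broken by the smaller
sensitivity–specificity gap, then by fold index.  The generalization
gap is the signed internal-minus-external difference per metric; the
written description of the gap mixes the average-internal and
selected-model variants, so `runPipeline()` reports both side by side,
with the selected-model variant first.

## Explainability

All saliency maps target a named convolutional layer and explain the
pre-softmax logit of a chosen class (the usual CAM convention; the
method statement is silent on it):

* `gradCAM()` — weights are spatial means of the class-logit gradient
  per feature map; the map is the rectified weighted sum, bilinearly
  upsampled and min-max normalized.
* `egradCAM()` — identical, but feature maps whose histogram entropy is
  at or below a threshold are excluded first.  The default threshold is
  exactly 0, i.e. only constant maps are dropped, matching the
  zero-entropy audit the method uses.
* `ablationCAM()` — each map's weight is its relative logit drop
  `(y_c − y_c^{map zeroed}) / y_c`, computed by literally re-running
  the forward pass from the target layer with that map zeroed.

`featureEntropy()` bins each map's activations into 256 uniform bins
over its own min–max range; a constant map is defined to have entropy
exactly 0.  The binning convention is not specified in published
EGrad-CAM descriptions, so it is fixed here and exposed as an argument.
`zeroEntropyRatio()` reports the percentage of zero-entropy maps at a
layer — the audit that distinguishes thin, fully-used networks from
wide transferred ones.

## The synthetic generator

No clinical images ship with the package; `generateLesionImage()`
renders seeded phantoms that carry the same class signal the method
exploits:

* geometry — an ellipse whose radius is modulated by a low-order
  sinusoid mixture, `r(θ) = r₀(θ)(1 + irregularity · S(θ))` with
  harmonics 2–5 and seeded phases; benign specs keep the amplitude
  below `irregularityThreshold()` (0.08), malignant above;
* echogenicity — interior darker than background (anechoic benign cysts
  around 0.08–0.18, hypoechoic malignant interiors 0.20–0.32, on a
  0.45–0.60 background);
* posterior effect — a multiplicative gain on the column band below the
  lesion (enhancement mostly with benign, shadowing mostly with
  malignant, strength 0.2–0.5, applied with probability 0.7);
* speckle — unit-mean multiplicative gamma noise with standard
  deviation 0.25, the standard first-order speckle approximation.

These defaults are the generator's study conditions, chosen once as
plausible B-mode appearance; no quantitative intensity statistics were
available to calibrate against.  The generator emulates *gross* lesion
appearance only: there is no beam physics, no depth-dependent
attenuation or focal zones, no multi-lesion frames, no acquisition
variability across machines.  Tests passing on these phantoms therefore
demonstrate that the machinery is correct and that the pipeline can
learn a genuine class signal — they say nothing about accuracy on
clinical data, and the clinical accuracy tables of the source study are
explicitly out of scope.

## Problem sizes and numerical notes

The CNN engine is plain R over BLAS matrix products (im2col
convolutions), which is why the packaged experiments run at desk scale:
the test suite trains 16-pixel inputs with 4–8 first-block kernels via
the `baseKernels` override of `buildArchitecture()`, 120-image
datasets, 3-fold cross-validation, and search budgets of 5–12 with a
synthetic closed-form objective for the full 50-evaluation behaviour.
The layer structure is identical at every width, so the narrow variants
exercise exactly the code paths of the full 91-kernel optimum.  Other
fixed numerical choices: batch-norm epsilon `1e-5` with running-stat
momentum 0.9; He-normal weight initialisation; max-pool gradient routed
to the first maximal element on ties; half-away-from-zero rounding
wherever the kernel rule or ratio grids round (`128/sqrt(2)` lands at
.51, but future grids may hit .5 exactly); all randomness flows from
one master seed through derived per-stage seeds, and `withr`-style
save/restore keeps package internals from disturbing the caller's RNG
stream.

## Known limitations

* The engine is CPU-bound and unsuitable for 128-pixel, 91-kernel
  training runs of the full optimum; it is an experimental harness, not
  a production trainer.
* `bounding` rectangles are axis-aligned; a rotated minimum-area
  rectangle interpretation of the annotation step is not implemented.
* The search treats `B` and `Epo` as continuous in the GP and rounds on
  decode, which can propose duplicate settings near grid points; the
  jitter makes this safe but slightly wastes evaluations.
* The generator's classes are easier than clinical data by
  construction (a two-feature linear classifier already separates them
  at ≥90%); headline percentages obtained on phantoms must not be read
  as clinical performance.
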