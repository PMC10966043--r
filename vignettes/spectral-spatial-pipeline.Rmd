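---
title: "Methods: spectral-spatial classification of hyperspectral plant scenes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spectral-spatial classification of hyperspectral plant scenes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(specfuse)
```

# The problem

Laboratory push-broom hyperspectral imaging is used to grade plant material
— here, classifying the growth year (1-7) of root samples such as ginseng,
where years 1-5 are traded as food and years 6-7 as medicine. Each sample
is scanned by two cameras: a VNIR instrument (288 bands, 400-1000 nm) and a
SWIR instrument (108 bands, 930-2500 nm). A Lambertian whiteboard is
scanned in the same pass and serves as the white reference. `specfuse`
implements the full chain from raw digital-number (DN) cubes to a trained
classifier, plus a synthetic scene generator so that every stage is
testable without instrument data.

# Scene model and segmentation

A scene holds three regions at fixed relative positions: the sample, the
whiteboard strip, and dark background. Because the whiteboard is scanned
before or after the sample in the scan (row) direction, it crosses the
full sensor width; this is what makes a *per-column* white reference
available for every column the sample occupies. `scene_layout()` therefore
declares a whiteboard **row** span.

Segmentation binarizes the gray-scale image of a single reference band
(622 nm for VNIR, 1597 nm for SWIR) with Otsu's method. One numerical
subtlety: the full scene histogram is trimodal (background, sample,
whiteboard), and a global Otsu threshold can land *between* sample and
whiteboard, emptying the sample mask. The threshold is therefore estimated
from the pixels outside the whiteboard span — where the histogram is
cleanly bimodal — and applied globally; the whiteboard clears it by a wide
margin. Stray-light flare brightens the whiteboard's edge pixels, so the
white-reference mask is eroded by a configurable `flare_margin` (default 5
px) on a zero-padded frame (image borders count as background — otherwise
edge-touching flare rows would survive erosion and bias the reference by
the full flare factor). Sample-mask speckle below `min_component_px`
(default 50) is removed.

# Radiometric calibration

Illumination and lens falloff vary across the sensor width (bright
center columns, dark edges) but act multiplicatively within a column. The
reflectance of sample pixel $(i,j)$ at band $\lambda$ is

$$\rho_\lambda(i,j) = \frac{DN_{GROI}(i,j)}{E\!\left(DN_{WROI}(:,j)\right)}$$

where the denominator is the mean whiteboard DN of column $j$ at the same
band. Any positive per-column illumination profile cancels exactly in this
ratio, as does a global gain — both are verified as exact invariances in
the test suite. No dark-current term is subtracted (the generator
accordingly adds no additive offset), the whiteboard is treated as having
reflectance exactly 1.0, and the reference is kept per band because the
source spectrum shapes the whiteboard DN. Columns without whiteboard
pixels are flagged invalid rather than zero-filled; calibrating a sample
column without a valid reference is an error by default
(`missing_ref = "nearest"` borrows the nearest valid column instead).

# Reflectance curves and the feature matrix

Each calibrated sample is reduced to its mean reflectance curve: the mean
over sample pixels, band by band, VNIR first then SWIR — 288 + 108 = 396
values under the defaults. The two cameras overlap near 1000 nm and both
segments are retained, so the curve may show a level discontinuity at the
range boundary; the VNIR-SWIR gap there shrinks with sample age and is one
of the classification signals. No smoothing, derivatives or
scatter-correction are applied: the model consumes raw mean reflectance.

# Band selection

With 396 bands, feeding every band image to a CNN is wasteful. Bands are
ranked by random-forest impurity importance: over `n_splits = 10` seeded
stratified train/test splits, a forest (500 trees, $\sqrt{p}$ features per
node) is fit on the training curves, and normalized importances (summing
to 1 across bands) are averaged. The forest is fit jointly on all 396
features — which also yields the VNIR/SWIR share of total importance — and
the top-k bands are then taken per range (default five VNIR, five SWIR),
with ties broken toward the lower wavelength. The selected band images are
stacked, co-registered by aspect-preserving nearest-neighbor rescaling
with zero padding onto the model grid (default 256 x 1024).

# The fusion classifier

The classifier has two branches. The spectral branch is a fully-connected
ladder 396 → 512 → 1024 → 512 → 128 (ReLU, bias, dropout between layers).
The image branch applies five blocks of [3x3 same-padding convolution →
batch-norm → ReLU → 2x2 max-pool] with filters 64/128/128/64/32, then
flatten → dropout → dense(512). The branch outputs are concatenated
(128 + 512 = 640), passed through dropout, and mapped by a dense softmax
head to the classes. Kernel size, stride and padding are not free choices:
they are forced by the reference per-layer weight counts (e.g.
3·3·6·64 + 64 = 3,520 for the first convolution on a 6-channel input), and
batch-norm is accounted at 4 parameters per channel (scale, shift, two
moving statistics) for the same reason. Setting `image_channels = 0`
degenerates to the pure spectral model, `spectral_input_len = 0` to the
pure image model; these are the ablation baselines.

The loss is the mean absolute error between the softmax output and the
one-hot target (the class-index form of MAE is not differentiable and is
rejected); accuracy is always computed from the per-round confusion
matrix as 100 · trace / total.

# Training stability under the MAE loss

MAE on softmax probabilities has a bounded, weak gradient, and a
confidently *wrong* prediction receives almost none (the softmax Jacobian
scales it by $p(1-p)$). With imbalanced classes the all-majority
prediction is therefore an absorbing attractor. This is observable, not
hypothetical: on separable synthetic curves that a random forest
classifies with zero out-of-bag error, a randomly initialized classifier
head starts from confident logits, makes early progress, and then
collapses to the majority class, where the vanished gradient cannot
recover it. Three defaults follow from this study:

* a zero-initialized classifier head: training starts from the uniform
  softmax, where the MAE gradient is alive for every class, rather than
  from random confident logits;
* class-balanced mini-batches (`balance_classes = TRUE`): on an
  imbalanced batch, "predict the majority everywhere" is itself a descent
  direction for the MAE loss and ends in the saturated attractor — the
  fusion model, whose convolutional features are uninformative early in
  training, reliably died this way even with the zero-initialized head.
  With balanced batches that shortcut costs half the batch and the
  attractor disappears; evaluation and splits are untouched;
* spectral-branch dropout 0.25 (head dropout 0.25) — dropout of 0.5 on
  the spectral ladder still collapses intermittently and is avoided;
* per-band standardization of the spectral input, fit on the training
  split and stored with the model (`standardize = TRUE`). Between-class
  reflectance differences (~0.02-0.06) are small against the curve level
  (~0.2-0.6), so raw curves condition the first dense layer poorly.
  This is input conditioning inside the model, not spectral
  preprocessing — the curve pipeline still delivers raw mean reflectance,
  and `standardize = FALSE` restores the raw path.

The reference protocol trains for 1800 iterations; the package keeps that
default in `experiment_plan()`.

# Experiment protocols

`run_experiment()` implements repeated random validation: per round, a
stratified hold-out split (stratified by growth year so every round's
validation covers the year classes; 17 of 84 samples by default — the
hold-out size under which all reference round accuracies are multiples of
1/17), model construction per plan, training, and evaluation by confusion
matrix. Rounds redraw the split each time. The year-by-year task uses all
7 classes with image stacks of five VNIR bands (Test 1), five SWIR bands
(Test 2), or the top-3 VNIR + top-2 SWIR by importance (Test 3);
`year_test_report()` lays the rounds out side by side. The binary
food/medicinal task sweeps the number m = 0..6 of optimal VNIR band
images (`food_medicinal_sweep()`), with an RGB-image-only baseline using
the bands nearest 622/546/443 nm.

# The synthetic generator

`generator_config()` fixes the study conditions: 84 samples with per-year
counts 17/11/12/12/8/12/12; DN cubes with an elliptical, smoothly textured
sample, a whiteboard strip with flare-boosted edges, a quadratic
column-illumination profile (center bright, default falloff 0.3);
reflectance curves in 0.15-0.7 with a Gaussian peak at 800 nm, a VNIR-SWIR
gap $g(\text{year}) = g_0 (1 - (\text{year}-1)/6)$ that vanishes at year
7, planted discriminative bands whose offsets scale with the standardized
year contrast, log-normal per-sample variability, and multiplicative
sensor noise of standard deviation $1/\text{SNR}$ (a simpler stand-in for
Poisson shot noise that suffices for ratio-based calibration tests). The
sample's spatial texture is normalized to unit mean over the ellipse, so
noise-free band means recover the true curve exactly. `effect_scale`
interpolates every year-dependent term about its year-4 value: 1 gives the
standard contrasts, 0 a null dataset with no year signal at all, used to
check that measured accuracy is statistically indistinguishable from
chance. Each sample draws its own seed from the master seed, so any
sample can be re-rendered identically and datasets can be streamed
through a callback without holding 84 cubes in memory.

What the generator does *not* emulate: morphologically realistic root
shapes and textures, chemically meaningful absorption features, Poisson
photon statistics, camera point-spread functions, or inter-camera
geometric misregistration beyond a rescale. Passing tests on synthetic
scenes therefore demonstrate the pipeline's *correctness* (calibration
algebra, curve extraction, selection and training machinery), not
field-level accuracy on real material.

# Problem sizes used by the test suite

The unit and acceptance tests run the pipeline at desk scale, chosen as
the package's reduced-scale protocol: scenes of 48 x 144 px with 60 + 24
bands for the classification checks (full 288 + 108 bands are exercised
in the curve-length and architecture checks), images downscaled to
64 x 256, 5 rounds x 100 iterations at batch 4 for the high-effect
feasibility check, and 3 rounds x 30 iterations on a balanced 21 + 21
zero-effect design for the null calibration (pooled accuracy compared to
the central 95% binomial interval around 50%). The full-scale
256 x 1024 x 6 network is built and audited for its exact parameter
counts but not trained. Numerical tolerances: noise-free calibration is
asserted to 1e-9 relative; SNR-100 recovery to 1% mean absolute;
gradient checks to 1e-4 relative against central finite differences.

# Known limitations

* The MAE loss remains fragile for hard, imbalanced problems even at the
  stable defaults; cross-entropy would be the pragmatic choice but is not
  the protocol reproduced here.
* Batch-norm moving statistics are warmed up only by the configured
  iteration budget; at very small budgets inference-mode normalization is
  close to the identity.
* The ENVI reader supports the common dialect (BSQ/BIL/BIP, data types
  2/3/4/5/12, little/big endian) but not vendor-proprietary raw formats,
  georeferencing, or tiled reads of cubes larger than memory.
* SWIR-to-VNIR co-registration is a rescale; real two-camera geometries
  need a proper spatial registration step before mixed-range stacks are
  scientifically meaningful.
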