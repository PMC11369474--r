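---
title: "Detecting flour adulteration in spice powders from visible images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting flour adulteration in spice powders from visible images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Ground spices — black pepper, red pepper, cinnamon — are routinely cut with
cheap, light-coloured fillers such as chickpea flour, which blends in
visually after grinding. powdersight implements a machine-vision screening
pipeline for this problem: ordinary RGB photographs of powder samples are
reduced to colour and texture statistics, a small set of discriminative
("efficient") features is selected, and the adulteration level of a sample
is classified into one of five mass-fraction classes (0, 5, 15, 30 and 50 %
by weight) by two independent classifiers — a feed-forward neural network
and a one-against-one support vector machine.

Because no public image set of this design exists, the package ships a
synthetic image generator that reproduces the statistical structure the
analysis relies on. Every downstream stage is therefore testable end to end,
and the whole pipeline is a pure function of one master seed.

```{r, eval = FALSE}
library(powdersight)
report <- run_all(run_config(master_seed = 42L), out_dir = "run")
report$summary
```

## The synthetic image model

A powder photograph is modelled as a two-material random field:

1. **Clump field.** Gaussian white noise is smoothed by a Gaussian kernel
   whose standard deviation is the adulterant's `granule_scale` (default
   4 px), giving a spatially correlated field. The top `fraction` quantile
   of the field is declared adulterant-occupied, so the areal occupancy
   share equals the nominal mass fraction to within one pixel. The spatial
   correlation matters: texture (co-occurrence) features carry no signal on
   i.i.d. salt-and-pepper noise.
2. **Colour.** Each pixel's RGB is drawn from the occupying material's
   normal colour model, clipped to [0, 1] (clipping rather than rejection
   sampling: at SD 0.05 around mid-range means the truncation mass is
   negligible). Default means — black pepper (0.28, 0.26, 0.24), red pepper
   (0.65, 0.30, 0.18), cinnamon (0.55, 0.40, 0.30), chickpea
   (0.85, 0.75, 0.55) — are chosen so the adulterant is the lightest
   material and cinnamon is the base product closest to it, making cinnamon
   mixtures the hardest to classify.
3. **Illumination.** The whole frame is multiplied by one factor drawn from
   Normal(1, `illumination_sd`) truncated to [0.7, 1.3]. The default SD of
   0.01 represents the small frame-to-frame photometric drift of a fixed
   imaging chamber; it is the dominant source of between-replicate
   variation, since per-pixel colour noise averages out over the crop.

The default design is 3 products x 5 levels x 18 replicates = 270 images of
256 x 256 pixels, written as 8-bit PNG with a CSV manifest. Per-image seeds
are derived from the master seed by integer hashing, so streams are
independent but fully reproducible.

What the generator does **not** emulate: lens geometry and vignetting,
specular highlights, focus variation, camera colour response, and the
within-material granule-size heterogeneity of real powders. Passing the
synthetic benchmark therefore shows that the pipeline recovers a
monotone colour/texture signal from clumpy two-component mixtures under
mild illumination noise — not that it reaches any particular accuracy on
real photographs.

## From image to 266 features

The centre of each image is cropped (default 192 x 192; the central window
avoids container edges in real imagery) and expanded into 19 scalar channel
planes: R, G, B; grey (0.2989 R + 0.5870 G + 0.1140 B); chromaticity
Nr, Ng, Nb; HSV; CIE L\*a\*b\* (D65/2°, sRGB linearization applied only
here); Ohta i1, i2, i3; and BT.601 Cb, Cr plus a green-difference chroma
Cg. Signed or unbounded channels are affinely mapped into [0, 1]
(`L/100`, `(a+128)/255`, `i2+0.5`, chroma `+0.5`, ...) so that histogram
binning, GLCM quantization and entropy scales are uniform across channels;
`channel_raw_scale()` inverts the mapping for reporting. Hue is treated as
a linear [0, 1] variable — no circular statistics.

Per channel, 14 statistics are computed:

* nine first-order colour statistics — min, max, mean, median, mode (centre
  of the most populated of 256 equal bins, lowest bin on ties), population
  SD, coefficient of variation, Pearson (non-excess) kurtosis, skewness;
  zero-variance planes return the documented degenerate values instead of
  NaN;
* five Haralick texture features — energy, contrast, entropy (base 2),
  correlation, homogeneity — of the grey-level co-occurrence matrix with
  32 quantization levels, distance 1, symmetric, averaged over the four
  standard orientations (0°, 45°, 90°, 135°) before the features are taken.

19 channels x 14 statistics = 266 features per image. Entropy is computed
from the co-occurrence matrix (not the first-order histogram): with 32
symmetric levels the joint distribution spans up to 2^10 states, which puts
typical powder-texture entropies in the 6–8 bit range.

## Efficient-feature selection

Sequential forward selection under a cross-validated deviance criterion: at
each step the candidate feature whose inclusion most reduces the summed
held-out deviance `-2 * sum log p_hat(true class)` of a ridge-stabilized
multinomial logistic model (lambda = 1e-4, features z-scored from each
training fold) is added; ties break by canonical feature order. Five
stratified folds are used inside the criterion — with resubstitution
deviance the greedy search would select until saturation. The search stops
when the relative improvement falls below 1e-3 or at 20 features. The
deviance generalizes the residual sum of squares to classification
likelihoods, so an uninformative candidate scores near the null deviance
`2 n log K`. The selected counts on the default synthetic data land in the
10–20 band, the same regime as the three real-data products.

## Classification

**Neural network.** A single-hidden-layer feed-forward network, tansig
(hyperbolic tangent) activation in both hidden and output layers, inputs
z-scored from training statistics, targets one-vs-rest vectors at ±0.9
(±1 would sit on the tansig rails and destabilize least-squares training).
Training is full-batch Levenberg–Marquardt: solve
`(J'J + mu I) delta = -J'r` with an analytic Jacobian, accept a step only
if training MSE does not increase, adapt `mu` by factors of 10. Overtraining
is prevented by early stopping — after 8 epochs without a new
validation-MSE minimum training halts and the best-validation-epoch weights
are returned. Full-batch LM on a small network occasionally parks an output
unit in a dead local minimum (one class absorbed by a neighbour, training
MSE plateauing near 4/5 of a unit error); training therefore runs from
three independent weight initializations and keeps the run with the lowest
validation MSE — the standard multi-start counter-measure, deterministic
given the seed. Data split 60/20/20 train/validation/test, stratified by
class. The default hidden size is 10; `ann_hidden = "scan"` searches 5–20
by validation accuracy, preferring fewer neurons on ties. Reported
artefacts: 5x5 confusion matrix, correct classification rate, per-epoch
MSE trace, and Pearson r between targets and outputs per partition.

**Support vector machine.** One binary soft-margin machine per unordered
class pair — 10 machines for 5 classes — on an 80/20 stratified split,
RBF kernel by default with cost and gamma chosen by 5-fold cross-validated
grid search over {0.1, 1, 10} x {0.01, 0.1, 1}. Prediction is majority
vote; vote ties are broken by the largest sum of signed decision values
among the tied classes, which makes prediction deterministic. The binary
machines are standard `e1071::svm` fits; the one-against-one combination
and tie-break live in this package.

Confusion matrices and rates are always reported in two scopes: over all
samples of a product (90 rows) and over the held-out test partition alone.
The all-samples scope mixes training data into the estimate and is
optimistic by construction; it is retained because it is the scope in which
five-level adulteration screens are conventionally summarized, and the
test-only figure is always printed beside it.

## Numerical choices and degenerate inputs

* All randomness (image synthesis, fold assignment, splits, weight
  initialization, tuning) flows from one master seed through a 31-bit
  integer-hash stream deriver; identical configuration + seed reproduces
  every artefact, images byte-identically.
* Zero-variance planes: cv, skewness, kurtosis are defined as 0; GLCM
  correlation as 1; entropy as 0.
* `cv = sd/mean` is 0 when |mean| < 1e-12; division guards mirror this
  threshold throughout.
* Crops use 0-based half-open windows; odd margins give the extra
  row/column to the bottom/right.
* The ridge lambda of the selection criterion is for conditioning only;
  note that duplicating a feature column shifts the criterion at O(lambda)
  because the penalty splits across the duplicates — the invariance is
  essential, not exact.

## Problem sizes used in the test suite

Unit and property tests run on small planes (≤ 16 x 16), 32–96 px synthetic
images and toy feature tables; the end-to-end benchmark runs the full
default design (270 images at 256 x 256, three products) once. These sizes
were chosen so the full suite exercises every stage at the study's design
scale while remaining comfortable to run routinely.

## Known limitations

* Synthetic imagery only: colour means are literature-plausible, not
  measured from reference powders; absolute feature values are not
  comparable to any physical measurement.
* The all-samples accuracy scope is optimistic (see above); use
  `rate_test` for an unbiased estimate.
* Hue statistics are linear, so hues near the 0/1 wrap (reds) can inflate
  SD/skewness; immaterial for these brown-dominated powders.
* The LM trainer is full-batch and dense — appropriate for ≤ a few hundred
  weights; it is not a general deep-learning trainer.
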