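---
title: "Growth staging from cervical vertebrae: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growth staging from cervical vertebrae: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cvmgrowth)
```

## The problem

Orthodontic treatment timing hinges on where a patient stands relative to
the pubertal growth spurt of the mandible. Serial lateral cephalograms from
longitudinal growth archives allow that status to be measured directly: the
mandibular length (the distance between Condylion and Pogonion, in mm)
increases with a pronounced velocity peak during puberty, so each film can
be labeled *pre-pubertal*, *pubertal*, or *post-pubertal* according to the
growth velocity observed over the interval preceding it. A classifier can
then be trained to predict that velocity-derived label from the appearance
of the cervical vertebrae (C2–C4) alone, turning a longitudinal measurement
into a single-film estimate.

`cvmgrowth` implements this pipeline end to end: velocity-based gold-standard
labeling of serial films, extraction of a 64×64 cervical-vertebrae region of
interest (ROI), balanced stratified dataset assembly, a lightweight
convolutional classifier with an 18-layer residual alternative, and the
evaluation layer (per-class one-vs-rest diagnostics, Cohen's kappa, Altman
interpretation). A synthetic-data module generates growth series and
vertebra-like images with the statistical structure the analysis assumes, so
the entire pipeline is testable without access to radiograph archives.

## Gold-standard staging

For a series of films at ages $t_1 < t_2 < \dots < t_n$ (months) with
mandibular lengths $L_1, \dots, L_n$ (mm), the velocity attributed to
interval $i$ is

$$v_i = \frac{L_{i+1} - L_i}{t_{i+1} - t_i} \quad \text{(mm/month)}.$$

`find_peak_window()` locates the interval of maximal velocity and extends it
to the maximal contiguous run of intervals with $v_i \ge \tau \cdot \max_j
v_j$. With the default `relative_threshold` $\tau = 1$ the window is the
argmax interval alone; lowering $\tau$ widens the "during the peak" window,
which is how a roughly balanced three-class dataset can be obtained from
series whose films cluster around the spurt. Ties at the maximum resolve to
the earliest qualifying run — a deterministic choice.

Each film after the first is labeled by the position of its *preceding*
interval relative to the window (before → pre-pubertal, inside → pubertal,
after → post-pubertal), because the velocity derived from a film describes
growth *prior to* its capture. The first film of every series has no
preceding interval; it is returned as `"unlabeled"` and excluded from
classifier datasets. This is the only reading consistent with the
preceding-interval convention. Labels are therefore monotone non-decreasing
along every series.

Eligibility screening (`check_eligibility()`) reports reason codes rather
than raising errors: at least six films between 96 and 180 months,
consecutive gaps within 9–18 months, adequate film quality, and exclusion of
skeletal class III and syndromic cases.

## The synthetic growth law

The generator models length as a linear background plus a logistic spurt:

$$L(t) = b + r\,(t - 96) + g\,\sigma\!\left(\frac{t - p}{s}\right),
\qquad \sigma(z) = \frac{1}{1 + e^{-z}},$$

so the velocity $dL/dt$ is the logistic density with a single analytic
maximum at $t = p$. This is the simplest growth law with a known velocity
peak, which makes ground truth exact: the generator records $p$ and the
noise-free trajectory, and recovery tests compare the staging module's
argmax interval against the interval maximizing the *noise-free*
interval-averaged velocity.

One subtlety motivates that choice of ground truth: with unequal film gaps,
the interval-averaged velocity can attain its maximum in an interval
*adjacent* to the one containing $p$ (a short interval near the peak can
average higher than a long interval containing it). This is a property of
interval averaging, not an implementation artifact, so the recovery
contract is: exact recovery of the noise-free argmax interval in 100% of
series, and recovery within one interval under 0.3 mm measurement noise in
at least 90% (both asserted in the test suite over 200 seeded series).

Default parameters emulate the study conditions of longitudinal
growth-center archives: baseline length 100 mm at age 8, background growth
0.03–0.08 mm/month, spurt gain 8–16 mm, logistic scale 4–8 months, peak age
prior mean 138 months for girls and 156 for boys (sex shifts only this
prior), measurement noise 0.3 mm, series of 6–9 films starting at 96–108
months with 9–18-month gaps. Landmarks are emitted in mm at a declared
1 mm/pixel scale; real-data ingestion accepts an explicit scale factor.

## The synthetic renderer

`render_synthetic_roi()` draws three stacked vertebral-body silhouettes
whose geometry varies monotonically with stage: the body height:width ratio
increases (0.70 / 0.85 / 1.00) and the lower-border concavity deepens
(0.05 / 0.15 / 0.28 of body height) from pre-pubertal to post-pubertal,
with additive Gaussian intensity noise (sd 0.05) and a small rotation
jitter (±3°). Both trends echo real vertebral maturation, but the
parameterization is a geometric stand-in, not an anatomical claim — real
CVM morphology is far richer. By construction the three classes are
separable (a nearest-centroid classifier reaches 100% on noise-free
renders), so what a passing pipeline test shows is that the implementation
learns and evaluates correctly — not that the architecture would reach any
particular accuracy on radiographs. Real-data accuracy claims are
explicitly out of scope.

## ROI extraction

The crop runs vertically from the Basion row to the C4 inferior-border row
(inclusive). The study design fixes only these superior/inferior limits;
the lateral extent is a design choice here: a symmetric window centered on
the mean landmark column with half-width 0.5 × the vertical extent
(configurable), which keeps the column centered without extra landmarks.
Resampling to 64×64 uses separable bilinear interpolation (nearest-neighbour
available as a reference method); intensities are min-max rescaled to [0,1]
per crop, with constant crops mapping to all zeros by convention. No
smoothing, sharpening or histogram filtering is applied anywhere.
Coordinates use the origin-top-left convention with rows increasing
downward; crop boxes are reported inclusive.

## Dataset assembly

`select_balanced()` draws up to `n_per_class` ROIs per stage (240 per class
at the pipeline's design scale). `stratified_split()` splits per class:
15% to test, then 20% of the remainder to validation, with half-up
rounding. Because 15% of 663 is not exactly 96, a `fixed_test_per_class`
override (32 at design scale) reproduces the balanced test layout; with
class sizes 223/225/215 this yields train 153/154/146 and validation
38/39/37 — exactly the design-scale layout. Splits are by image, not by
subject: films of one subject may span partitions, which inflates apparent
accuracy on real data where within-subject films are correlated. A
subject-grouped split can be had by selecting manifest rows per subject
before splitting; the caveat matters for real-data use and is deliberately
surfaced here.

## Classifier

The designed network is exactly three convolutional stages
(3×3 convolution → batch normalization → ReLU → 2×2 max pooling, channels
16/32/64) followed by two fully connected layers (4096 → 128 with ReLU and
dropout 0.5, then 128 → 3 with softmax) on a 64×64 single-channel input.
Only the layer counts, input size, batch normalization and dropout are
fixed by the design; kernel sizes, channel widths, the hidden width, the
loss (cross-entropy) and the optimizer (Adam at its conventional 1e-3
initial rate) are package defaults, all overridable through
`model_config()` and `train_config()`. A ReLU follows the hidden dense
layer — without a nonlinearity the two dense layers would collapse to one
linear map.

The residual alternative is the standard 18-layer topology (stem
convolution, four stages of two two-convolution residual blocks at
64/128/256/512 channels, global average pooling, dense output) adapted to
the 1-channel 64×64 input: a 3×3 stem without the initial stride-2/max-pool
reduction, which would discard too much of a small input. It is always
trained from random initialization with no frozen layers. A reduced-depth
`residual_small` variant supports desk-scale experiments.

Augmentation draws, per presentation: rotation uniform in ±20°, row/column
shifts uniform in ±10% of the image size, and zoom uniform in 1±10% —
applied as a single inverse-mapped affine warp with bilinear sampling and
reflection at the borders. Zero magnitudes reproduce the input exactly.
"Decreasing learning rate" is implemented as step decay ×0.5 every 50
epochs (configurable); training keeps the weights from the best
validation-accuracy epoch (earliest on ties). All randomness — weight
initialization, shuffling, augmentation, dropout — flows from explicit
integer seeds, and no global RNG state is disturbed, so identical seeds
give bit-identical histories and predictions.

The engine itself (im2col convolution on BLAS, fused batch-norm kernels,
max-pooling with argmax caching, Adam, full backpropagation including
residual blocks) is implemented in R with Rcpp kernels; gradients flow
through exactly the layers described above.

Class-activation maps use the gradient-weighted scheme: the gradient of the
predicted class's logit with respect to the last convolutional stage's
activations is averaged spatially into per-channel weights, the weighted
rectified channel sum is upsampled bilinearly to the input size, and the
maximum is normalized to 1 (an all-zero map stays zero, so degenerate
inputs are safe).

## Evaluation layer

The 3×3 confusion matrix (rows = true stage, columns = predicted) is
collapsed one-vs-rest per class: sensitivity TP/(TP+FN), specificity
TN/(TN+FP), PPV TP/(TP+FP), NPV TN/(TN+FN), per-class accuracy
(TP+TN)/total, each ranked across classes (1 = best; ties share the better
rank). Measures with zero denominators are reported as `NA` ("undefined"),
never silently as 0 or 1.

Cohen's kappa is computed unweighted and with linear and quadratic weights.
A useful identity: with balanced true classes the unweighted expected
agreement is exactly 1/3 regardless of the predicted marginals, so
$\kappa = (\text{accuracy} - 1/3)/(2/3)$ — with 78/96 correct this gives
0.71875 and with 84/96 it gives 0.8125. Published "weighted kappa" values
that coincide with these numbers are therefore reproduced by the unweighted
form; the package computes all three and leaves the terminology question to
the reader. Altman bands use upper-inclusive boundaries: ≤0.20 poor,
≤0.40 fair, ≤0.60 moderate, ≤0.80 good, above very good.

## Numerical choices and degenerate inputs

* Peak-window qualification uses a relative tolerance of 1e-12 on the
  maximum rate so exact ties are not split by floating-point noise; the
  argmax interval always qualifies regardless of sign.
* Telescoping (interval deltas summing to the total length change) holds to
  1e-9 relative and is asserted property-style.
* Bilinear resampling uses the pixel-center convention and preserves
  ordering on monotone inputs; 8-bit PNG round trips are exact because
  writes quantize explicitly to 255 levels.
* Batch normalization uses biased batch variance, momentum 0.9 running
  statistics and eps 1e-5; inference uses running statistics.
* Softmax subtracts the column maximum before exponentiation; training
  aborts with an explicit divergence error (naming the epoch) if the loss
  becomes non-finite.
* Argmax label ties break toward the earlier stage.

## Problem sizes used by the checks

The test suite and the acceptance script run the pipeline at its design
scale where that is cheap (240 ROIs per class, fixed 32-per-class test
split, 50 training epochs at batch 32) and at reduced scale elsewhere
(30 ROIs per class, ~18 epochs for the shared classifier fixture; 200
seeded series per staging-recovery condition; 1000 random matrices/series
for oracle equivalence). These sizes were chosen so each property is
measured with comfortable margins while the whole suite stays quick to run.

## Known limitations

* The renderer's stage-conditioned morphology is a stand-in; passing tests
  demonstrate implementation correctness, not clinical performance.
* Image-level (not subject-level) splitting is the default, as discussed
  above.
* No confidence intervals are attached to the diagnostic measures or
  kappas, and no ROC analysis is provided.
* Landmark positions are taken as given (no automatic landmark detection),
  and no magnification correction is applied beyond the mm-per-pixel scale.
* How many films per subject a real labeling would place "during" the peak
  is not recoverable from velocity data alone; the relative-threshold
  window makes that choice explicit and configurable rather than silently
  fixed.
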