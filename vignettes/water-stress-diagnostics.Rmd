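---
title: "Diagnosing crop water stress from thermal and RGB imagery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diagnosing crop water stress from thermal and RGB imagery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cwsifusion)
```

## The problem

Irrigation decisions on working farms need a water-stress signal that can
be measured with affordable field equipment: a handheld thermal camera, an
RGB camera, a soil moisture probe, and public weather data. `cwsifusion`
implements a complete diagnostic stack around those inputs, developed for
field-grown sweet potato under five soil-moisture treatments — severe dry
(SD, volumetric water content ≤ 10%), dry (D, 20 ± 2%), optimal
(O, 30 ± 3%), wet (W, 40 ± 3%) and severe wet (SW, ~50%).

## A field-observable CWSI

The classical crop water stress index

$$\mathrm{CWSI} = \frac{T_c - T_\mathrm{wet}}{T_\mathrm{dry} - T_\mathrm{wet}}$$

normalizes canopy temperature $T_c$ between the temperatures of a fully
transpiring ($T_\mathrm{wet}$) and a non-transpiring ($T_\mathrm{dry}$)
reference canopy. Those references are rarely measurable in production
fields. The index implemented here replaces them with field observables:

* $T_\mathrm{dry}$ is a fixed site constant (default 34&nbsp;°C, the hottest
  leaf observed on the calibration plots; exposed as a parameter because
  it is site-specific);
* $T_\mathrm{wet} = T_a - \delta$, where $T_a$ is air temperature and the
  correction coefficient

$$\delta = \min\!\big(6,\; 2 + 0.1\,\lvert \mathrm{VWC} - 30\rvert
  + 2\,(1 - \mathrm{RH}/100)\big)$$

grows with soil-moisture deviation from its 30% optimum and with drier
air (RH in percent). The cap of 6 applies to the *sum*, never to
individual terms. The numerator of the index is taken as
$\lvert T_c - T_\mathrm{wet}\rvert$ by default so that both overheated
(droughted) and unusually cool (waterlogged) canopies register as
stressed; a signed variant is available through
`cwsi_parameters(numerator = "signed")` for users who want the classical
one-sided reading. The result is clipped to $[0.05, 1]$ — the floor
absorbs sensor error near the unstressed limit.

Two modelling notes. First, $\delta$ is symmetric about 30% VWC even
though the physiological story emphasizes drought; the symmetric form is
implemented as specified, and the absolute-value numerator is what makes
waterlogging visible. Second, all terms of $\delta$ are non-negative, so
no lower cap is needed.

```{r cwsi-example}
r <- compute_cwsi(28.5, weather_observation(25, 100),
                  soil_moisture_reading(30))
c(delta = r$delta, t_wet = r$t_wet_c, cwsi = r$cwsi)
```

Validation is strict (errors, not silent `NaN`s): the index feeds
irrigation decisions, and a wrong number is worse than no number.

## Imaging: calibration, preprocessing, quality control

Leaf temperature is extracted from a thermal frame as the **mean of three
region means** over manually annotated, pairwise-disjoint leaf regions —
not the pooled pixel mean, so a large region does not outweigh a small
one. Regions are accepted as JSON annotations (rectangles/polygons in
0-based half-open image coordinates) or as run-length masks. Emissivity
(default 0.9) and acquisition height (1.05 m) are carried as metadata
only; no radiometric re-computation is attempted.

RGB calibration anchors on a 24-patch reference checker: an affine map
(3×3 linear part plus offset — affine rather than linear, so brightness
offsets are absorbed) is fitted by least squares from observed patch
colors to reference values and applied to every pixel, clipped to 0–255.
Gamma correction defaults to 1 (a no-op unless configured, since no value
is prescribed), and histogram equalization operates on the luminance
channel with chrominance preserved to avoid hue shifts. Vegetation is
separated from soil by thresholding the excess-green index
$2G - R - B$ with Otsu's method — a standard baseline, pluggable via
`index_fun` where excess green is the wrong discriminant.

The original image screening was visual. `qc_filter()` ships programmatic
*proxies*, not a reproduction of that manual procedure: a
foreground-fraction bound (leaf regions distinguishable), a
variance-of-Laplacian focus score (blur), and an optional exclusion mask
(non-crop objects). Every rejection is logged with its rule id.

`preprocess_for_model()` produces the network inputs: bilinear resize to
128 × 128 and division by 255. Thermal frames are first min–max scaled
per frame to 0–255; the frame extremes are kept as attributes so
temperature stays recoverable. Per-frame scaling discards absolute
temperature — the network sees spatial contrast (droughted leaves appear
as hot spots, waterlogged ones as cold spots against soil), which is one
reason the image classifier works on a coarser class scheme than the
tabular models.

## Statistics and evaluation protocol

* `remove_outliers_3sigma()`: values outside mean ± 3 sample standard
  deviations of the *full* input are flagged in a single pass (the band
  is never re-estimated after removal — deterministic and idempotent).
* `one_way_anova()`: classical one-way decomposition (via `stats::lm`),
  shipped as a utility for treatment comparisons.
* `metrics_from_confusion()`: per-class one-vs-rest precision, recall and
  F1 with macro/weighted aggregates; multiclass accuracy is trace/total,
  which is what the binary (TP+TN)/(TP+TN+FP+FN) form reduces to in the
  one-vs-rest aggregate. A class that is never predicted gets precision 0
  with a warning rather than `NaN`.
* `make_stratified_folds()`: seeded (default 42) stratified k-fold plans
  whose per-fold class histograms deviate from the global distribution by
  at most one record per class; one plan is reused across all models so
  comparisons are paired.
* `cross_validate()`: any feature scaler is fitted on the training subset
  of each fold only and then applied to the held-out fold — the test
  suite asserts that per-fold scaler statistics differ, which is the
  observable footprint of leakage-free preprocessing.
* The 80/20 split is stratified under the same seed convention; the
  1:1:2:1:1 treatment design (optimal class doubled) is expressed through
  `design_counts()`.

## Growth-stage tabular classifiers

Per-plant records join four growth indicators (stem length, NDVI,
chlorophyll fluorescence, SPAD) with leaf temperature and CWSI. A seeded
random forest ranks feature importance per growth stage (early = June,
tuber bulking = July, late = August); impurity-based importance is the
default with permutation importance as an option, since the original
analysis does not state which was used. The top four features per stage
(ties broken by canonical feature order) feed five classifier families —
multinomial logistic regression, random forest, k-nearest neighbours,
a single-hidden-layer perceptron, and an RBF support vector machine —
each behind the same scaler-then-classifier pipeline (forests skip
scaling, being scale-invariant). Hyperparameters are unreported in the
source study, so library defaults are used and exposed: KNN k = 5
(Euclidean, on standardized features), RF 500 trees, MLP 64 hidden units
with weight decay 10⁻³ (the `nnet` optimizer has no early stopping, so
decay plus an iteration cap provides the regularization), SVM RBF C = 1,
LR multinomial. KNN is fitted through `caret::knn3` because decision
fusion needs the full class-probability vector, not just the winning
vote.

## The RGB–thermal fusion classifier

Two small CNNs extract features from the RGB (3-channel) and thermal
(1-channel) 128 × 128 inputs separately: three blocks of 3 × 3
convolution (16 → 32 → 64 filters), ReLU and 2 × 2 max pooling. The
thermal branch's final feature maps pass a **channel mask**: the mean
activation of each channel over batch and spatial axes is compared to a
strict threshold of 0.1, and only channels above it are kept, uniformly
for all thermal inputs. The mask is computed once on a reference batch
after a one-epoch warm-up and then frozen (recomputing it every batch
would make the architecture non-stationary); if nothing clears the
threshold, the single highest-mean channel is kept and the mask flagged
degenerate, so the branch cannot go dead. Each branch is reduced by
global average pooling, concatenated (128 values), reshaped into 8 tokens
of 16 values, linearly embedded to width 64, and processed by one
transformer encoder block (4 heads, feed-forward width 128,
post-layer-norm) before a 256-unit dense layer and softmax head. With
these defaults the model has 213,539 trainable parameters —
deliberately sized near 2.2 × 10⁵. Exact branch depths and transformer
dimensions are configurable (`fusion_config()`), as the reference
architecture is described only at block level.

Training follows the published configuration: Adam at learning rate
0.001, sparse categorical cross-entropy, batch 64, at most 100 epochs,
early stopping with patience 10 on validation loss and restoration of the
best-validation weights. A `min_delta` of 10⁻³ (not specified in the
source configuration) defines what counts as an improvement; on
validation folds of ~100 samples, smaller loss changes are resampling
noise, and an explicit threshold keeps run lengths bounded and
deterministic. The network is implemented in-package: R orchestrates the
transformer, dense head, Adam and the training loop, while the
convolution/pooling kernels are C++ (im2col + BLAS GEMM) in single
precision — standard practice for CNN arithmetic. Correctness is
enforced two ways in the test suite: finite-difference gradient checks of
every parameter group on a small configuration, and agreement of the
fused single-precision kernels with independent double-precision
reference kernels.

Image-only classification uses a three-level scheme — dry side, optimal,
wet side — obtained from the five treatments by the configurable mapping
SD, D → dry side; O → optimal; W, SW → wet side. The source material is
ambiguous about the merge direction (one section names the coarse classes
"D, O, W", another displays "Severe Dry / Optimal / Severe Wet"); the
default mapping merges each extreme with its neighbour, and the display
labels follow the deployed decision screen ("Severe Dry", "Optimal",
"Severe Wet"). Class probabilities collapse by summation
(`collapse_proba_5to3()`).

`grad_cam()` explains predictions: the gradient of the target-class logit
with respect to a branch's final convolutional feature maps is averaged
over space to weight each activation map; the rectified weighted sum is
normalized to [0, 1] and upsampled to the input size. The arithmetic core
(`cam_from_activations()`) is exported and tested against closed-form
cases.

## Decision layer

The deployed decision averages two probability streams: the stage KNN
model's 5-class output collapsed to 3 classes, and the fusion network's
3-class output (probabilities, not hard labels — averaging labels would
discard calibration). The element-wise mean is renormalized; exact ties
break to the first class in canonical order and set an `ambiguous` flag.
The label maps to an irrigation action: dry side → initiate irrigation,
optimal → maintain current conditions, wet side → reduce watering.
`run_pipeline()` (and the `inst/cli/cwsifusion` wrapper) orchestrates the
whole path — simulate, calibrate, extract temperatures, compute the
index, train both model families, explain, predict — writing JSON logs
with seeds, a config hash and the package version for every run.

## The synthetic data generator

No field data accompany the method, so `generate_dataset()` emulates the
acquisition stack with explicit class-conditional structure: soil VWC
drawn uniformly within each treatment band (the ±2/±3 figures are read as
half-widths; the bare "50%" of the severe-wet treatment gets a ±1 band so
draws are non-degenerate); three disjoint elliptical leaves on a soil
background rendered at 160 px (larger than the model input, so the real
resize path is exercised); thermal frames with background at air
temperature and leaf pixels at a class-conditional temperature (default
33/31/28/26/24 °C for SD–SW, ~25 °C air) plus Gaussian noise; leaf hues
running from yellow-brown (severe dry) through green (optimal) to dark
teal-green (severe wet); and stage-conditional indicator draws whose
adjacent-class separations are several standard deviations in leaf
temperature and CWSI. Directionality (dry = hotter and yellower) follows
crop water-stress physiology; magnitudes are configuration, not claims
about sweet potato. A single `separation` dial scales every
class-conditional deviation: at 0 all classes coincide and classifiers
fall to chance, at 1 (default) the stack is recoverable — the test suite
checks both ends.

What passing on synthetic data does *not* show: robustness to real canopy
texture, occlusion and illumination, to unpaired RGB/thermal frame
counts, or to the actual effect sizes of field treatments. The generator
demonstrates that the machinery is correct and recoverable, not that the
published field accuracies transfer.

## Numerical choices and problem sizes

* Bilinear resampling for all resizes (affects bit-exactness of any
  pixel-level comparison; fixed and documented).
* Conv arithmetic in single precision; gradient tests therefore use
  finite-difference steps of 10⁻³ and a 5% relative tolerance, with the
  double-precision kernels as exact oracles.
* Ties in top-k feature selection break by canonical feature order;
  decision-fusion ties break to the first canonical class with a flag.
* Test-suite problem sizes (chosen for single-CPU runs): the fusion
  recovery check trains on 600 paired frames (200 per 3-level class,
  from the 1:1:2:1:1 five-level design) at 128 px with the full training
  configuration; the end-to-end pipeline check uses 36 samples with a
  40-epoch budget; tabular checks use 40–60 records per stage. The
  generator itself defaults to the 300-sample 1:1:2:1:1 design.
* All randomness is seeded; generation, fold plans, training and
  manifests are reproducible run-to-run on one machine (seeded utilities
  save and restore the caller's RNG state).

## Limitations

* The CWSI calibration constants (T_dry = 34 °C, base 2, cap 6, the 30%
  optimum) are site- and crop-specific; all are parameters.
* The correction coefficient treats wet and dry soil-moisture deviations
  symmetrically; combined with the absolute-value numerator this makes
  the index a *deviation* score, not a drought score.
* The QC screens are proxies for a visual procedure and should be
  re-thresholded for new cameras.
* Thermal min–max scaling discards absolute temperature from the image
  pathway (it remains in the tabular pathway via leaf temperature and
  CWSI).
* The fusion network trains on CPU at these problem sizes; it is not a
  GPU-scale implementation, and no pretrained backbones are involved.
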