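---
title: "Decoding task states from 4D BOLD with a 3D residual network: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding task states from 4D BOLD: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A block-design task fMRI run is a 4D time series: every TR (0.72 s in the
acquisitions this package targets) a full 3D brain volume is sampled while the
participant performs task blocks of 12–28 s. Classical decoding (SVM-MVPA)
first reduces each block to a feature vector — usually GLM beta images — and
then classifies; this demands feature engineering and discards the temporal
structure of the haemodynamic response. `fmridecode` instead feeds the raw 4D
fragment covering one block plus an 8 s haemodynamic tail to a 3D
convolutional residual network and lets the network learn both the temporal
compression and the spatial features end to end. Guided back-propagation then
maps each classification back onto the voxels that supported it, giving the
decoder an interpretable, GLM-comparable spatial readout.

## From runs to samples

A sample is the set of frames whose *entire* acquisition interval lies inside
the block window: frame $t$ (0-based) is included iff
$[t \cdot TR, (t+1) \cdot TR) \subseteq [onset,\ onset + duration + 8\,s)$.
This frame-containment rule is exact and order-preserving: a 12 s block at
TR = 0.72 s yields 27 frames (the largest $n$ with $0.72(n+1) \le 20$ is 26),
and the frame count is monotone in the block duration. For the longest
standard condition (27.5 s) the same rule yields 49 frames; descriptions of
this sample-extraction scheme elsewhere quote a 27–50 frame range, and no
single rounding convention reproduces both endpoints, so the upper bound is
treated as a configuration limit rather than an identity. Onsets need not be
TR-aligned; a mid-TR onset simply shifts the first included frame.

Volumes on the 91×109×91 MNI 2 mm grid are cropped to 75×93×81 to discard
non-brain margins. Only the target shape is canonical; the crop is centred by
default (offset (8, 8, 5)) and configurable, and the affine is translated so
retained voxels keep their world coordinates.

## The network

The input fragment is a $k \times X \times Y \times Z$ array with $k = 27$
frames. Its time axis is treated as the channel axis of the first layer — a
1×1×1 convolution mapping 27 temporal channels to `n_ch1 = 3` per-voxel
temporal descriptors. Then a 3×3×3 convolution with stride 2, four residual
blocks (two 3×3×3 convolutions each; output channels 32, 64, 64, 128; stride
2 in the last three), a *full convolution* whose kernel equals the incoming
feature extent (5×6×6 on the 75×93×81 grid), collapsing space to 1×1×1 — a
deliberate replacement for global pooling that keeps the head linear in the
feature map and therefore clean to back-propagate through for visualization —
and finally two fully connected layers (64 units, then the class head with
softmax). Batch normalization and ReLU follow every convolutional layer;
"same"-style padding of 1 means only strides change the spatial extent.

### Calibrating the under-specified widths

The reference description of this architecture family reports a total of
3,981,852 trainable parameters for 27-frame 75×93×81 input with a 7-class
head, but leaves several structural details unstated: the width of the
strided convolution, the channel count of the full convolution, bias
placement under batch normalization, and the shortcut type. We treat the
printed total as the binding constraint. With the hard constraints fixed
(two-convolution post-activation residual blocks; BN+ReLU after every
convolution; biasless convolutions under batch norm, except the full
convolution, which opens the classifier head and keeps its bias;
parameter-free zero-padded identity shortcuts — He et al.'s option A — on
stride or channel changes), the two remaining free integers are determined
*uniquely* by the count: `conv2_channels = 63` and
`final_conv_channels = 123`. `calibrate_architecture()` performs this
enumeration; the test suite asserts both the count (by enumerating every
trainable array *and* by an independent per-layer closed form) and the
uniqueness of the solution within the documented search ranges. Projection
(1×1×1 convolution) shortcuts remain available behind
`use_projection_shortcuts` but are not the calibrated default, since their
extra parameters are incompatible with the printed total. Because the
calibrated conv2 width (63) exceeds the first block's output width (32), the
first block's identity shortcut truncates to the leading 32 channels — the
mirror image of zero-padding on channel growth.

The parameter count of every layer except the full convolution is independent
of the input grid, and growing the class head changes the total by exactly
(64 + 1) per class; both facts are pinned by unit tests.

## Training

The loss is softmax cross-entropy — the standard choice for a softmax
classifier head. Optimization uses Adam with β₁ = 0.9, β₂ = 0.999, initial
learning rate 10⁻³ and batch size 32. Augmentation is purely temporal:
spatially the volumes are already co-registered, so each epoch takes a fresh
random fragment of $k = 27$ consecutive TRs from every training sample
(uniform start), while validation and testing always use the first $k$ TRs so
reported numbers do not fluctuate. The learning rate is divided by 10
whenever the validation loss has not set a new minimum (absolute tolerance
10⁻⁴) for 15 consecutive epochs; training stops early once the rate has been
decayed twice more without improvement, or at the epoch budget (30 for
initial training, 120 for transfer), and the returned model is always the
checkpoint with the minimum validation loss — which makes the exact stopping
rule non-critical.

Cross-validation is subject-wise: subjects (never samples) are partitioned
into five test groups, and the non-test subjects are split into training and
validation at the configured ratios (70/10/20 for initial training, 60/20/20
for transfer). Five equal test groups cannot always be cut from an arbitrary
subject count (43 subjects give test groups of 8–9), so fold sizes may differ
by one from the nominal ratio; the partition invariants — disjointness within
a fold, each subject testing exactly once — are exact and audited by tests.
One master seed fans out to fold assignment, weight initialization and crop
randomness, and training histories are bit-reproducible under it on a given
BLAS.

Transfer learning re-uses every trained layer except the output layer, which
is re-initialized for the new label set; the whole network is then fine-tuned
with the same loop. Besides the transferred weights, the trunk also carries
its batch-norm running statistics, which is part of why transfer reaches
criterion accuracy in fewer epochs than training from scratch — a freshly
initialized network spends its first epochs just settling those statistics.

## Evaluation

Per-label tallies come from the multi-class confusion matrix: TP is the
diagonal entry, FP/FN the off-diagonal column/row sums. TN follows the
convention in which it equals the summed true positives of the *other*
labels; the usual one-vs-rest TN (all correct rejections) is available via
`tn_convention = "standard"`, and for two classes the conventions coincide.
F1 = 2TP/(2TP+FP+FN); sensitivity, specificity and accuracy as usual. Any
zero denominator yields 0 with a warning rather than an error, so fold
aggregation never crashes. ROC curves are one-vs-rest sweeps of the
target-class score with tied scores grouped (midpoint convention), making the
trapezoidal AUC exactly the Mann–Whitney U statistic over positive/negative
pairs — an identity the tests verify, alongside a cross-check against an
independent ROC implementation. Chance level is 100/n_classes reported to two
decimals (14.29% for 7 classes, 25% for 4, 50% for 2). Confusion matrices are
normalized by row (per true-label counts).

## Pattern maps and group effects

Guided back-propagation differentiates the target class score (pre-softmax
logit) with respect to the input, but at every ReLU the gradient is passed
only where *both* the forward input and the incoming gradient are positive —
keeping only paths that positively support the class. Batch-norm layers use
frozen inference statistics during this pass. The 4D gradient is collapsed
over time by keeping, per voxel, the signed value of largest magnitude (ties
broken toward the earliest frame), and the 3D map is then divided by its
maximum *absolute* value, bounding it in [−1, 1] while preserving sign — the
literal signed maximum would explode maps whose largest positive value is
near zero, so max-abs is the default and the normalizer is recorded in the
map's attributes. An all-zero gradient is returned as an all-zero map with a
degeneracy flag rather than divided. Group maps are voxelwise Cohen's d: the
mean of the per-sample pattern maps divided by their sample SD (n−1);
zero-variance voxels are set to 0 and counted. `footprint_contrast()`
formalizes "the decoder looked at the right place" as a one-sided Welch test
of mean d inside versus outside a known footprint.

## Baselines

The comparison stack mirrors standard SVM-MVPA practice. Voxelwise OLS on a
design matrix of HRF-convolved boxcar regressors (one per condition) plus an
intercept and two discrete-cosine drift terms produces per-condition beta
images; on noiseless simulated data the betas recover planted amplitudes to
machine precision, and residuals are orthogonal to the design by
construction. Whole-brain and ROI variants flatten betas over a mask and
classify with a linear multi-class SVM (one-vs-one voting, C = 1 — the
regularization constant is not standardized in the sources this mirrors, so
the library default is kept). The searchlight slides a radius-3-voxel sphere
(123 offsets, verified against brute-force enumeration) over the mask,
classifies from the betas inside the sphere (clipped, not dropped, at mask
edges so maps cover the whole mask), and writes each condition's pooled
cross-validated F1 at the centre voxel. No ROI is canonical for the ROI
variant, so the mask is a required input; synthetic tests use the true
footprint.

## The synthetic generator

The simulator emulates the *structure* of a multi-subject block-design
acquisition: conditions with realistic block durations (18, 28, 20, 12, 16,
23, 27.5 s for the seven classic tasks), TR = 0.72 s, rest gaps, and
per-condition spatial activation footprints — axis-aligned ellipsoids on a
disjoint lattice, a stylized stand-in for distinct task topographies. Voxel
signal is baseline + amplitude × (boxcar ⊗ HRF) on footprint voxels, with a
canonical double-gamma HRF (peak 6 s, undershoot 16 s, ratio 1/6, unit-peak
normalized at the TR), AR(1) Gaussian noise (ρ = 0.3), two low-order cosine
drift terms, and a per-subject multiplicative gain ~ N(1, 0.1) (truncated at
0.1) that makes subject-wise cross-validation meaningful. Everything is
deterministic under (design, subject, seed).

What the generator does **not** emulate — and what passing tests therefore do
not establish about real data: physiological noise and motion artifacts,
spatial autocorrelation of BOLD noise, realistic anatomical geometry and
brain masks, distributed/overlapping task representations, and
between-subject *spatial* variability (footprints are identical across
subjects; only gain varies). Synthetic decodability is far cleaner than real
task fMRI; the tests establish correctness and internal consistency of the
pipeline, not field performance.

## Numerical choices

The 3×3×3 convolutions run through a compiled im2col + GEMM kernel in single
precision — the GEMM dominates runtime, float32 halves it, and per-layer
relative error ~10⁻⁶ is far below the noise scale of the data; all other
layers and the optimizer state are double precision. Gradient correctness is
established by double-precision finite differences against a naive
triple-loop convolution oracle and, for the composite network, by exact
agreement at layers whose gradient magnitudes rise above float32 resolution.
Batch norm uses ε = 10⁻⁵ and momentum 0.1 with unbiased running variance.
Weight initialization is He-normal throughout. The temporal-collapse
tie-break (earliest frame) and the ROC tie-grouping are fixed conventions so
results are exactly reproducible.

## Problem sizes in the test suite

The end-to-end acceptance checks run a deliberately desk-scale study: a
24×28×24 grid, four conditions (block durations 18/28/20/12 s), 20 subjects,
two blocks per condition, amplitude 3 against unit-SD noise (SNR 3), one
70/10/20 subject-wise fold, a 20-epoch budget; the transfer experiment uses a
two-condition target task (12 s blocks, amplitude 2) on 10 fresh subjects
with 60/20/20 splits and a 15-epoch budget; GLM bias is estimated over 100
noise realizations on a 12×14×12 grid. These sizes were chosen so the full
suite trains real networks in minutes while leaving every qualitative
property (decodability, chance-level control, localization,
transfer-vs-scratch ordering, estimator bias) decisively testable.

## Known limitations

- The calibrated widths (63, 123) are the unique solution of a counting
  constraint, not values with independent empirical support; any other
  structural resolution of the unstated details would need a different width
  pair and would not match the printed total.
- Bit-reproducibility holds for a fixed BLAS/CPU; different BLAS builds can
  reorder floating-point reductions and yield different (equally valid)
  trained weights.
- Training is single-threaded CPU; the implementation targets method fidelity
  and desk-scale experiments, not GPU-scale cohorts.
- The statistical behaviour of guided back-propagation is not characterized;
  pattern maps are descriptive and are not thresholded for significance.
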