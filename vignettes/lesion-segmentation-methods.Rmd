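---
title: "Methods: valid-padding 3D U-Net segmentation of cortical and white-matter MS lesions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: valid-padding 3D U-Net segmentation of cortical and white-matter MS lesions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Multiple sclerosis produces demyelinating lesions both in the white matter
(WMLs), which are bright and conspicuous on FLAIR images, and in the cortical
grey matter (CLs), which have very low FLAIR contrast and are best seen on
MP2RAGE-UNI images. `cortseg` implements a complete framework for segmenting
both lesion types simultaneously from a co-registered FLAIR + MP2RAGE pair:
a three-level valid-padding 3D U-Net ("3D U-Net-"), its training recipe,
tiled whole-volume inference, a lesion-wise evaluation suite, and a seeded
synthetic phantom generator so that every stage can be exercised and tested
without clinical data.

## The network

The architecture is an encoder-decoder with two-channel input and a
single-channel sigmoid output (lesion probability; lesion *typing* comes from
the ground truth, as CL subtypes are pooled). All convolutions are unpadded
("valid") 3^3 kernels followed by ReLU; there is no batch or instance
normalization. Three resolution levels are connected by 2^3 max pooling and
2^3 stride-2 up-convolutions, with encoder feature maps center-cropped and
concatenated at each skip. The filter plan is:

* analysis path: 32, 64, 64, 128, 128 convolutions (the fifth is the first
  bottleneck convolution);
* synthesis path: 256, 128, 128, 64, 64, 1 feature maps (the leading 256 is
  the second bottleneck convolution; the trailing 1 a 1^3 projection).

Two readings of this plan are possible at the up-convolutions. We halve the
channel count there (256 to 128, 128 to 64) so that post-concatenation widths
equal the paired encoder stage; this yields 3,703,777 trainable parameters
(about 3.7 M), consistent with the 3.8 M reference budget, whereas
channel-preserving up-convolutions would give about 4.6 M and exceed it.
`count_parameters()` computes the analytic count and every built model is
checked against it.

Because no padding is used anywhere, each cubic input of side `s` maps to an
output of side `s - 40`; an 88^3 patch yields a 48^3 prediction, and the
network integrates a spatial context of 41 = 88 - 48 + 1 voxels.
`trace_shapes()` exposes the full per-layer arithmetic and names the failing
layer for infeasible inputs (any side that is odd when it reaches a pooling
layer, or that vanishes under the convolutions). Weight initialization is a
seeded He-uniform (fan-in) scheme; the recipe itself does not prescribe one.

The forward and backward passes are implemented in the package itself
(direct C++ convolution kernels plus exact hand-derived backpropagation
through pooling, up-convolution, cropping and concatenation), and the
backward pass is verified against central finite differences and against an
independent im2col/GEMM formulation in the test suite.

## Training recipe

* **Normalization.** Every input volume is standardized to zero mean and unit
  variance over *all* voxels. No brain mask is used because the pipeline
  performs no skull stripping; whole-volume statistics are the only mask-free
  choice. The population (N) standard deviation is used — at volume scale the
  difference from N-1 is far below tolerance.
* **Sampling.** Training patches are *lesion-balanced*: a ground-truth
  connected component is drawn uniformly (so a 3-voxel cortical lesion is
  sampled as often as a 3000-voxel confluent WML), then the 88^3 input window
  is centered on a uniformly drawn voxel of that component with a +/-12 voxel
  per-axis jitter, clipped to the reflection-padded volume. The jitter
  prevents the network from learning that lesions always sit at the patch
  center; the recipe does not specify the centering rule, so this convention
  is ours.
* **Loss.** Per-voxel weighted binary cross-entropy on the 48^3 output with
  weights 1 (background), 1 (WML) and 5 (CL), computed in stable logits form,
  plus an L2 penalty of 1e-5 (applied as `1e-5/2 * sum(W^2)` on convolution
  kernels only, not biases — the common convention).
* **Schedule.** The learning rate ramps from 1e-8 at iteration 0 to 1e-4 at
  iteration 2000 and is halved every 10,000 iterations thereafter. Only the
  endpoints of the warm-up are prescribed; we interpolate log-linearly
  (geometrically), which spans the four orders of magnitude smoothly, and we
  count halving periods from the end of warm-up.
* **Optimization.** Adam with default moments, batch size 2.
* **Augmentation.** On the fly per patch: rotation about the z axis uniform
  in +/-90 degrees, isotropic scaling uniform in 0.95-1.05, independent flips
  along all three axes. Intensities are interpolated trilinearly; the label
  patch by nearest neighbor and the target/weight maps re-derived from it, so
  weights remain exactly in {1, 5}.
* **Early stopping.** The weighted validation loss is evaluated every
  `val_interval` iterations on deterministic, un-augmented patches centered
  at each validation component's centroid; training stops after `patience`
  consecutive non-improving checks and the best checkpoint is returned.
  Component-centred validation patches (rather than a full tiling of every
  validation volume) keep the early-stopping signal focused on lesions at a
  small fraction of the cost; the defaults (patience 5, interval 1000) are
  package choices, which the recipe leaves open.

## Inference

Whole volumes are predicted by tiling: output windows of side
`input_side - 40` step across the volume disjointly, edge tiles are shifted
inward so the union covers every voxel, and overlaps created by the shift are
resolved by deterministic lexicographic priority. Each input window extends
20 voxels beyond its output window into a reflection-padded volume —
reflection rather than zeros, to avoid feeding the network out-of-distribution
values at the edges. The binary mask is `probability >= threshold`, with the
threshold chosen on the validation set by grid search over 0.05, 0.10, ...,
0.95, maximizing the mean per-subject Dice after minimum-size filtering; ties
break toward the lower threshold to favor sensitivity.

## Evaluation suite

Lesions are connected components; the default connectivity is 18 (the
convention of the MS lesion challenge metric definitions this protocol
follows; 6 and 26 are available). Typed grids are labelled per class so a
touching WML and CL remain distinct. Components smaller than 3 voxels are
re-classified as background in both the ground truth and the prediction
before every metric — at 1 mm isotropic voxels that is 3 uL, at 1 x 1 x 1.2 mm
3.6 uL, both far below the classical 3 mm minimum WML diameter (a sphere of
about 14 mm^3).

Per subject we report voxel-wise DSC, PPV and AVD (absolute volume
difference, normalized by the ground-truth volume, hence asymmetric) and
lesion-wise LTPR, LTPR_WM, LTPR_CL and LFPR. A ground-truth lesion counts as
detected when at least one of its voxels is covered by any predicted
component; a predicted component overlapping both a WML and a CL detects both
and is not a false positive. Undefined metrics (empty denominators) are
reported as missing and excluded from cohort medians, never silently set to 0
or 1. Cohort aggregation uses medians and interquartile ranges; volumes are
compared by Pearson correlation with a least-squares fit; paired method
comparisons use the two-sided Wilcoxon signed-rank test with Bonferroni
correction at significance level 0.05.

Size-stratified detection bins ground-truth lesions by voxel count into
half-open `[lo, hi)` intervals and reports the per-bin rate with the per-bin
ground-truth count.

## Experiments

`make_folds()` builds site-stratified k-fold plans: within each site subjects
are shuffled (seeded) and dealt round-robin, so per-site proportions per test
fold match the cohort within one subject; 20% of the non-test subjects
(nearest rounding) become the validation set. For 90 subjects at k = 6 this
gives the 15/60/15 test/train/validation split; for a 54-subject training
cohort the 20% rule gives 11 validation subjects. Stratification is by site
only — the protocol states no finer rule. One model is trained from scratch
per fold with fold-specific seeds derived from the master seed.

## The phantom generator

The phantom stands in for clinical cohorts whose images are not distributable.
It is deliberately geometric rather than physical: a nested-shell "brain" (an
ellipsoidal cortex ribbon of configurable thickness around a white-matter
core) with ellipsoidal lesions — the simplest geometry that gives the two
lesion types distinct spatial priors. Lesion volumes follow a log-normal
truncated below at 3 voxels (heavy-tailed per-subject burdens, as in real
cohorts); WMLs are placed inside the core, CLs must intersect the ribbon;
candidates that would merge two intended lesions into one component are
rejected and resampled. Default tissue means encode the clinical contrast
ordering — the WML/white-matter contrast in the FLAIR-like channel (80
intensity units) is much larger than the CL/cortex contrast there (15), while
the CL contrast in the MP2RAGE-like channel (40) clearly exceeds its FLAIR
counterpart — and the generator rejects configurations violating this
ordering. Noise is additive Gaussian per channel (sd 5 against tissue
contrasts of 15-80); no bias field, partial-volume model or MR physics is
simulated, and the method under test does not correct for such effects
either.

Cohorts derive per-subject seeds deterministically from a master seed and
draw per-subject lesion counts from Poisson distributions (means 8 WMLs and
3 CLs per subject by default, at least one lesion per subject), so burden
varies across subjects by orders of magnitude in the tails, as in patient
populations.

What passing on phantoms does and does not show: the phantom exercises every
contract of the pipeline — patch geometry, sampling balance, loss behavior,
stitching exactness, metric definitions, fold bookkeeping, reproducibility —
and shows that the architecture can learn the lesion-versus-tissue contrast
structure. It does not certify clinical accuracy: real lesions have textured
interiors, ill-defined borders, partial-volume rims and anatomical context
that ellipsoids with Gaussian noise do not reproduce.

## Numerical and scaling choices

* Degenerate inputs: zero-variance volumes are rejected by the normalizer;
  lesion-free cases are rejected by the lesion-balanced sampler; empty
  ground truths yield missing metrics, not zeros.
* Threshold ties break low; tile overlaps resolve by lexicographic priority;
  component ids follow scan order — all deterministic.
* All randomness flows through explicit integer seeds; derived seeds stay in
  the 32-bit range.
* The test suite and examples run scaled-down configurations chosen once:
  phantoms of 48^3-64^3 voxels, the architecture at one eighth (or one
  sixteenth) of the filter plan, 52^3 input patches (the same 40-voxel
  margin), a few hundred training iterations with a peak learning rate of
  1e-3 to 3e-3, warm-up 10-100 iterations and halving period 100-300
  iterations — a faster schedule than the full-scale recipe because a
  58,000-parameter model on high-contrast phantoms converges in hundreds,
  not tens of thousands, of iterations. Inference in tests uses 68^3 input
  tiles to reduce tile counts. The full-scale defaults in `train_config()`
  and `unet_spec()` are exactly the reference recipe.

## Known limitations

* The framework assumes co-registered inputs; registration, bias-field
  correction and skull stripping are out of scope.
* Inference tiling and stitching is a reconstruction — the original
  windowing scheme is unspecified; any scheme agrees wherever the network is
  translation-consistent (shifts that are multiples of 4 voxels, given two
  pooling levels).
* The 3.8 M reference parameter figure is treated as an upper bound: the
  derived exact count under channel-halving up-convolutions is 3,703,777,
  and no standard convention reproduces 3.8 M exactly.
* Training at the full reference scale (88^3 patches, 32-256 filters, tens
  of thousands of iterations) is supported by the code but is a GPU-scale
  workload; the package's own validation is at reduced scale.
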