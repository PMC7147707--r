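---
title: "Methods: plantar thermogram segmentation and thermal change grading"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: plantar thermogram segmentation and thermal change grading}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermofoot)
```

## The problem

Infrared thermography of the sole is a non-contact way to monitor the
diabetic foot: abnormal local temperature rises precede ulceration. Healthy
feet show a characteristic *butterfly pattern* — warmest along the medial
arch, cooling toward the periphery — while diabetic (DM) feet lose that
pattern and develop hot regions with no fixed spatial layout. This package
implements a full analysis chain for plantar thermograms:

1. **Segmentation** of the hottest plantar region by fuzzy-entropy
   multilevel histogram thresholding, optimized with Differential
   Evolution (DE).
2. **Grading** of the thermal change of a DM foot against a control
   reference via the angiosome-based Thermal Change Index (TCI), into five
   levels.
3. **Feature extraction** from the segmented region-of-interest (ROI) for
   classical MLP/SVM classification, and **patch extraction with
   rotation/flip augmentation** for convolutional classification.
4. **DFTNet**, a compact nine-layer convolutional network trained from
   scratch, implemented natively in R.
5. **One-vs-one evaluation** with the six standard measures (sensitivity,
   specificity, precision, accuracy, F-measure, AUC).

A synthetic thermogram generator with controlled thermal structure drives
every test; no patient data ships with the package.

## Fuzzy-entropy multilevel thresholding

A thermogram is quantized to `L` gray levels (`to_gray()`; per-image
min–max by default, because histogram *shape*, not absolute calibration,
drives the segmentation — an absolute range can be supplied for
cross-image comparability). Its normalized histogram
$p_0, \dots, p_{L-1}$ is partitioned into $n$ fuzzy segments by
overlapping trapezoidal membership functions $\mu_1 \dots \mu_n$
parameterized by $2(n-1)$ sorted breakpoints
$(a_1, c_1, \dots, a_{n-1}, c_{n-1})$: $\mu_1$ is 1 up to $a_1$ and
descends linearly to 0 at $c_1$; each subsequent set rises over the same
ramp, so $\sum_i \mu_i(k) = 1$ at every gray level by construction
(partition of unity); $a_i = c_i$ degenerates to a crisp step. This
complementary-trapezoid family is the canonical parameterization for
fuzzy-entropy thresholding: thresholds fall at the middle of the overlap
of consecutive sets, $T_i = \mathrm{round}((a_i + c_i)/2)$, with rounding
collisions repaired by incrementing duplicates upward.

The objective is the total fuzzy entropy. With segment masses
$P_i = \sum_k p_k \mu_i(k)$,

$$H = \frac{1}{n \ln L} \sum_{i=1}^{n} \left[ -\sum_{k} \frac{p_k \mu_i(k)}{P_i}
\ln \frac{p_k \mu_i(k)}{P_i} \right],$$

where zero-mass terms are dropped and empty segments contribute 0. The
$n \ln L$ normalization makes values comparable across segment counts
(sub-1.0 on any histogram); the raw sum is available with
`normalize = FALSE`.

### Differential Evolution

`optimize_partition()` maximizes $H$ with DE/rand/1/bin. Hyperparameters
(population 30, $F = 0.5$, $CR = 0.9$, 150 generations) are standard
robust defaults, all configurable through `de_config()`. Two numerical
choices matter:

* **Integer lattice.** Thresholds are gray levels, so candidates are
  *repaired* by rounding to the integer grid, sorting and clipping, rather
  than searched in the continuous box. This keeps every candidate feasible
  (no rejection) and makes the optimum directly comparable with exhaustive
  integer search — at `L = 32`, `n = 2` the DE optimum coincides with
  enumeration of all 528 `(a, c)` pairs.
* **Seeded RNG.** All stochastic routines take a seed and restore the
  caller's RNG state, so pipelines are reproducible end to end.

### Choosing the number of levels

Entropy alone always prefers fewer segments (the two-segment split of a
cold background against the foot has near-maximal entropy but a useless
ROI). `select_segmentation_level()` therefore balances entropy against a
*defined* ROI: by default it picks the largest candidate $n$ whose
hottest-segment ROI covers at least 2% of the foot mask and whose largest
connected component holds at least 90% of ROI pixels. The component-share
rule (rather than demanding a single component) tolerates the speckle that
sensor noise produces at segment boundaries; setting
`min_component_share = 1` restores the strict rule. When no candidate
qualifies the maximum-entropy segmentation is returned with a warning
flag, and the per-`n` entropy table is attached either way.

## Angiosomes and the Thermal Change Index

The sole is divided into the territories of four arteries: medial plantar
(MPA), lateral plantar (LPA), medial calcaneal (MCA), lateral calcaneal
(LCA). Published angiosome atlases give no printable coordinates, so
`partition_angiosomes()` uses a configurable proportional rule: the
proximal `heel_fraction` (default 0.27) of the mask's bounding-box height
forms the calcaneal band, and each row is split at the mask midline into
medial/lateral halves, with `side` deciding which image side is medial
(plantar view: the medial border of a left foot appears on the image's
right). The rule is exhaustive and exclusive on any mask and can be tuned
to any atlas.

The TCI compares a subject's mean angiosome temperatures $DM_{ang}$
against a control reference $C_{ang}$:

$$TCI = \frac{1}{4} \sum_{ang \in \{MPA, LPA, MCA, LCA\}} (C_{ang} - DM_{ang}).$$

The differences enter *signed* (a hot subject gives a negative TCI); an
absolute-difference mode is available because the printed form of the
index is ambiguous about sign handling. Since the five change levels grade
the *degree* of change, `assign_level()` bins $|TCI|$ against four
strictly increasing boundaries (level $= 1 +$ number of boundaries below
$|TCI|$); a signed mode exists. The boundary defaults, 1–4 °C equally
spaced, are configuration: the population-derived cut points live in the
angiosome literature and should be supplied by the user for clinical
fidelity.

## The synthetic generator

`generate_synthetic()` emulates the two archetypes the analysis chain must
distinguish, on a tapered elliptical foot mask covering roughly half the
frame:

* **butterfly** (control): baseline sole at `base_foot_temp` (default
  30 °C) plus a Gaussian arch ridge of amplitude `arch_amplitude`
  (default 4 °C) centered on the medial half at mid-foot height, over a
  uniform cold background (default 22 °C). The planted *arch band* —
  pixels with elevation at least half the amplitude — is attached for
  closed-loop segmentation tests.
* **hot_region** (DM): the butterfly is lost (flat sole) and
  `hot_region_count` Gaussian hot blobs are added. Their common amplitude
  scale is calibrated by bisection *on the noise-free field* so that the
  TCI against the generator's own control reference lands in the requested
  `target_class`; blob width grows with the class, reflecting that the
  highest grades correspond to hot regions covering most of the sole. An
  unreachable class raises an error naming the violated bound.

Additive Gaussian sensor noise (default sd 0.3 °C, a typical thermal
camera noise floor) is applied last; equal specs are bit-identical. The
defaults were chosen once as a realistic desk-scale stand-in: background
clearly separated from the sole (so the 32-level histogram's global
maximum sits in the background mode), a 4 °C arch, and sub-degree noise.
What the generator does **not** emulate: inter-subject anatomy, toe
geometry, partial amputations, radiometric drift, or the texture of real
skin — so green tests demonstrate algorithmic correctness, not clinical
performance on real thermograms.

## ROI features, patches and augmentation

`extract_features()` returns the five-element vector used by the classical
classifiers: ROI pixel count, mean and population variance of ROI gray
values, the maximum total fuzzy entropy of the segmentation, and the
*index value*. The last is under-specified in the field's usage; it is
implemented as the modal gray level inside the ROI (ties toward the lower
level), with the ROI's segment index available via
`index_mode = "segment_index"`, and the choice recorded on the result.

`extract_patches()` tiles the image row-major with a given size and
stride, keeping tiles whose mask coverage reaches `min_mask_fraction` — a
reproducible replacement for expert patch selection.
`augment_patches()` expands each square patch into exactly seven variants
in fixed order: original, rotations by 90/180/270°, horizontal, vertical
and combined flips. These are the elements of the dihedral group $D_4$
minus the diagonal reflections; $r_{90}^4 = id$, $f_h^2 = id$ and
$r_{180} = f_h \circ f_v$ hold exactly and are tested.

## DFTNet

The patch classifier is a nine-layer network: conv 7×7/32 → maxpool 3×3
s2 → conv 1×1/64 → conv 3×3/64 → maxpool 3×3 s2 → conv 3×3/32 → maxpool
2×2 s2 → conv 3×3/32 → fully-connected softmax. The layer table leaves
several things unstated; the package's choices are:

* **ReLU** after every convolution, no batch normalization.
* **Same-padding** convolutions, **valid-padding** pools — with these, a
  64×64 input survives the pooling cascade (64 → 31 → 15 → 7), which is
  also the default input size (`c(64, 64, 3)`, grayscale patches
  replicated across channels). Too-small inputs fail with an error naming
  the offending layer.
* **Softmax cross-entropy** loss, the implied objective of a
  classification output layer.
* **He-uniform** seeded initialization for convolution kernels; the output
  layer starts at **zero**, so an untrained network predicts the uniform
  distribution and the initial loss on balanced data is exactly
  $\ln(\text{classes})$ — a useful self-check, at no cost to
  trainability.

Training (`dftnet_train()`) is minibatch Adam (defaults: learning rate
0.001, batch 64, at most 100 epochs) with an optional early-stopping rule
on training or validation accuracy. The implementation is native R: each
convolution is an im2col gather (precomputed integer index maps per layer)
followed by a BLAS matrix product, and the backward pass scatters
gradients through the same maps; it was verified against numerical
differentiation. On one CPU core a 200-patch epoch at 64×64×3 takes on
the order of 10 s, and the separable two-class problem used in the tests
converges within a handful of epochs. The point of this module is a
faithful, auditable reference implementation of the architecture — not
GPU-scale throughput.

## Classical baselines and evaluation protocol

The feature-based baselines are a 3-layer MLP (`nnet`; input–hidden–output
with a default hidden width of 10, since the hidden size is not part of
the architecture's public description) and a linear-kernel SVM (`e1071`),
both preceded by z-score standardization fitted on training data only
(margins are scale-sensitive; the features mix pixel counts with
entropies).

Classification is evaluated **one-vs-one**: `make_ovo_tasks()` builds one
binary task per class pair, ordered by decreasing class separation (for
five classes: 1-5, 2-5, 1-4, 3-5, 2-4, 1-3, 4-5, 3-4, 2-3, 1-2).
`evaluate_baseline()` combines an 85/5/10 train/validation/test split with
stratified 10-fold cross-validation; how these two prescriptions compose
is not fixed by the protocol's public description, so the package makes
one documented choice: the folds provide the test portions, and the
85/5 ratio carves a validation set out of each fold's training remainder.
Out-of-fold predictions are pooled into confusion counts, from which
`metrics_from_counts()` computes sensitivity, specificity, precision,
accuracy and F-measure. The accuracy formula is the standard
$(TP+TN)/(TP+TN+FP+FN)$. Metrics with zero denominators are reported as
flagged zeros, never dropped, so table averages stay auditable. `roc_auc()`
sweeps thresholds over distinct scores with tied scores sharing an
operating point, making the trapezoidal area identical to the
Mann–Whitney pair-counting statistic; `pair_table()` renders the ten-pair
table with its Average row.

## Problem sizes and test design

The test suite runs entirely on generated data: DE-versus-enumeration at
32 gray levels on 20 random histograms, threshold recovery on 50 two-mode
histograms (modes 8 and 24, sd 2), 1000 random angiosome quadruples for
the TCI, the full 0–10 confusion-count grid for the metric formulas, 200
random ROC instances of up to 50 samples, 200 separable 64×64 patches for
DFTNet trainability with a label-shuffled control, and 20 seeded butterfly
thermograms for the end-to-end segmentation check (arch recovery measured
by Jaccard overlap with the planted band). `scripts/acceptance.R`
recomputes all of these from scratch. Unit tests exercise the same
mechanics at reduced sizes (e.g. 18×18 CNN inputs) so the default suite
stays fast.

## Known limitations

* The angiosome partition is proportional, not atlas-registered; clinical
  use requires tuning `heel_fraction` and the class boundaries to a
  population reference.
* The TCI reference must come from a control cohort; the package ships no
  population values.
* DFTNet is single-threaded CPU code; it is meant for method study and
  verification, not production-scale training.
* Real-data loaders cover CSV/TIFF/PNG temperature rasters only; camera
  vendor formats need external conversion.
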