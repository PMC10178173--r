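---
title: "Pyramidal deep features, iterative ReliefF and cubic-SVM evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pyramidal deep features, iterative ReliefF and cubic-SVM evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pyrads)
```

## The problem and the model

`pyrads` targets two-class classification of musculoskeletal radiographs at
desk scale, with flatfoot (pes planus) screening from weight-bearing
lateral foot X-rays as the motivating application. On such radiographs the
diagnosis is geometric: the calcaneal inclination angle below 18° indicates
a collapsed medial longitudinal arch. Labeled medical image sets of this
kind are small (hundreds of cases), which rules out training a network from
scratch; the pipeline instead relies on *frozen* ImageNet-pretrained
backbones as generic feature extractors and puts all the learning into
feature selection and a shallow classifier.

The pipeline has four stages.

**Resizing, augmentation and balancing.** Images are stretched bilinearly
to 512 × 512 × 3 without preserving aspect ratio — the pyramid stage needs a
fixed square input, and a direct stretch is the simplest convention that
provides one. Class imbalance is removed by generating augmented copies:
each synthetic record applies exactly one randomly drawn geometric
operation (rotation, isotropic scaling with center crop/pad back to the
frame, or horizontal mirroring) to an original, cycling over the originals
in deterministic order under a seeded generator. One operation per record
keeps every augmented image close to a real one and makes the provenance
log trivially replayable; the operation ranges (rotation ±10°, scale
0.9–1.1) are mild enough not to move anatomy out of frame, and are
configurable.

**Pyramidal feature generation.** Each 512² image is divided, without
overlap, into its 2 × 2 grid of 256² patches and its 4 × 4 grid of 128²
patches. The original plus the 20 patches form an ordered 21-image pyramid;
each image is mapped through the backbone's pre-softmax 1000-way
class-score layer ("Logits"), and the 21 vectors are concatenated so that
slot *i* occupies columns ((i−1)·1000 + 1) … (i·1000) — 21,000 features per
case. Patch order within a level is row-major; any fixed order works, since
a permutation of slots only permutes feature columns, but it must be
*stable* for the selected column indices to be meaningful across runs.
Every pyramid image is resized to the backbone's native input side before
inference, the standard transfer-learning convention; this keeps the 21
slots dimensionally uniform. The pyramid couples global arch geometry
(level 1) with local texture and edge evidence (levels 2–3), which is what
lifts accuracy over single-image features.

**ReliefF and iterative ranked-prefix selection.** Features are first
min–max normalized per column, which puts the per-feature distance
`diff(A, I1, I2) = |x(A,I1) − x(A,I2)|` in [0, 1] and bounds weights in
[−1, 1]. ReliefF then rewards features that agree among nearest same-class
neighbors (hits) and differ across nearest other-class neighbors (misses),
the miss term of each class C weighted by P(C)/(1 − P(class(R))). The
ranking alone does not say *how many* features to keep, so the wrapper
stage evaluates growing prefixes of the descending-weight ranking with the
cross-validated cubic-SVM loss and keeps the minimizing prefix (first
minimum on ties, i.e. the smallest such subset).

**Cubic-SVM evaluation.** The pinned classifier is a polynomial-kernel SVM
of degree 3 with box constraint 1 and standardized inputs, evaluated under
seeded stratified 10-fold cross-validation. Held-out predictions are pooled
into a single confusion matrix; accuracy, precision, recall and F1 are
computed from the pooled counts, with the *normal* class taken as positive
(configurable). Pooling, rather than averaging per-fold metrics, matches
reporting a single confusion matrix and makes accuracy + loss = 1 an exact
identity.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `image_side` | 512 | px | working resolution; divisible by 4 for the two patch levels |
| `target_per_class` | 700 | records | balanced target after augmentation |
| rotation range | ±10 | degrees | mild geometric jitter, anatomy stays in frame |
| scale range | 0.9–1.1 | factor | as above |
| `k_neighbors` | 10 | neighbors | standard ReliefF setting; robust hit/miss averages at n in the hundreds |
| `step`, `max_prefix` | 1, all columns | features | full ranked-prefix sweep; thin with `step` when the sweep cost (prefixes × CV fits) matters |
| SVM `degree` | 3 | — | cubic kernel |
| `cost` | 1 | — | box constraint |
| `kernel_scale` | `"auto"` | — | median pairwise distance heuristic, below |
| `n_folds` | 10 | folds | stratified cross-validation |

## Numerical and design choices

- **ReliefF determinism.** The update cycle visits every instance exactly
  once in row order (m = n) instead of sampling m random instances. This
  removes a nuisance source of randomness, matches common library
  implementations, and preserves the 1/(m·k) scaling. Neighbor distance is
  the Manhattan distance over normalized features — the sum of per-feature
  `diff`s, so the metric and the update use the same geometry — with ties
  broken by lower row index. When a class has at most k members, k is
  clipped per class (hits: class size − 1, misses: class size) with a
  warning and the update divides by the clipped count.
- **Continuous `diff`.** The discrete 0/1 rule is provided, but deep
  features are continuous, so the standard continuous extension (absolute
  difference of normalized values) is the default.
- **Constant columns** min–max normalize to all-zeros (avoiding 0/0),
  receive weight exactly 0, and sort after equal-weight columns (stable
  sort), so degenerate features can never be selected ahead of informative
  ones.
- **Prefix indexing.** The selected prefix indexes the *ranked* columns
  `order[1:best]` of the original-scale matrix; the classifier does its own
  standardization, so selection operates on raw features while ranking
  operates on normalized ones.
- **Kernel scale "auto".** Resolved per training fold as the median
  pairwise Euclidean distance among up to 1000 seeded-subsampled
  standardized training rows; deterministic, scale-adaptive, and covariant
  under column duplication (doubling every column doubles squared
  distances and halves the kernel's gamma, leaving the kernel unchanged —
  a property the tests assert). A zero or non-finite median falls back to
  1. The kernel is ((x/s)ᵀ(y/s) + 1)³, implemented through libsvm via
  `e1071` with gamma = 1/s² and coef0 = 1; standardization uses
  training-fold statistics only, and zero-variance columns get unit scale.
- **Pyramid side.** `build_pyramid()` accepts any square side divisible by
  4 (levels S, S/2, S/4), with 512 the standard and the pipeline default.
  The generalization lets replicated simulations run at smaller sides
  without touching the operation; the 512-px contracts are asserted as
  such in the tests.
- **Degenerate inputs.** Single-class label vectors, non-square tiles,
  missing values, empty manifests, undecodable files, zero-denominator
  precision/recall and all-zero confusion counts all raise explicit errors
  or warnings rather than propagating NaN.
- **Seed fan-out.** A single master seed is mapped to per-stage seeds by a
  fixed affine rule reduced mod 2³¹ − 1, so stages can be re-run in
  isolation and the whole pipeline is bit-reproducible.

## What the synthetic generators emulate — and what they do not

The phantom generator emulates the *statistical* structure of the imaging
problem, not anatomy: a dark noisy background, a bright bone-like polyline
whose inferior arc angle is drawn from a per-class Gaussian (defaults 15°
vs 25°, SD 3°), standing in for the calcaneal inclination angle around the
18° diagnostic boundary. When the class means straddle the boundary, draws
are truncated to their class's side so that thresholding the generated
angle reproduces the labels exactly; with equal means (a null
configuration) no truncation is applied and the labels are independent of
the pixels. The feature-matrix generator plants q informative columns
(class means ±δ/2, unit variance) among D − q standard-normal noise
columns and returns the ground-truth indices, which is what the recovery
and calibration tests exercise.

Passing tests on these generators show that the pipeline's contracts hold —
ordering, shapes, determinism, oracle agreement, chance-level behavior
without signal, signal recovery with it. They do not show radiographic
realism: no X-ray physics, no soft tissue, no inter-patient anatomy, no
label noise from human readers. Performance numbers on phantoms say
nothing quantitative about clinical images.

Likewise, the *stub extractor* — block-mean downsampling to a 12 × 12 grid
followed by a fixed seeded Gaussian projection — honours the extractor
contract (fixed width, determinism, input sensitivity) but is a linear
map; it is a test double, not a claim that pretrained features are linear.
Pretrained backbones plug in through `register_backbone()`.

## Problem sizes used in the test suite

The suite runs desk-scale versions of every property: ReliefF/oracle
agreement on 20 random problems with n ≤ 30, D ≤ 8 at 10⁻¹² tolerance;
recovery on 50 seeds of (n = 200, D = 50, q = 5, δ = 2) requiring all
informative columns in the ReliefF top 10 in ≥ 95 % of seeds; null
calibration over 50 replicates of (n = 200, D = 20, q = 0) requiring pooled
CV accuracy within three standard errors of 0.5; permutation-null
comparison of the selection minimum at n = 60 with 200 label permutations;
and an end-to-end run on 40 phantoms at 512 px with a 16-wide stub, which
must reach pooled CV accuracy ≥ 0.9 and reproduce bit-identically on
rerun. These sizes were chosen as the smallest at which the statistical
assertions are stable across seeds.

## Known limitations

- No pretrained weights ship with the package, so headline accuracies on
  real radiograph datasets require the user to register a backbone backed
  by an actual network.
- The full ranked-prefix sweep is O(D) cross-validated SVM fits; at
  D = 21,000 this is expensive, which is why `step`/`max_prefix` exist.
  The sweep also inherits the usual wrapper-selection caveat: the selected
  size is tuned on the same cross-validation used to report the loss
  curve, so the final evaluation should use (as the pipeline does) a fold
  assignment seeded independently of the selection folds.
- Exact accuracy on any given clinical dataset depends on that dataset's
  fold partition and the backbone; fold-level reproduction of published
  numbers is not possible without the original partition.
- Balanced augmentation replicates minority-class originals with mild
  geometric jitter; it does not create new anatomical variation, and
  augmented copies of one original can land in different CV folds,
  slightly optimistic for generalization estimates.
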