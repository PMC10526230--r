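---
title: "Hierarchical multi-task 3D CNNs for nodule attributes: models, phantom, and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical multi-task 3D CNNs for nodule attributes: models, phantom, and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Radiologists grade lung nodules on ordinal semantic scales — margin
sharpness, sphericity, subtlety (conspicuity), internal texture
(ground-glass to solid), calcification pattern, and malignancy suspicion.
An interpretable computer-aided diagnosis model should expose these
intermediate judgements rather than emit a single opaque malignancy score.
`hsnet3d` implements two hierarchical multi-task 3D convolutional
architectures for this purpose, their full training recipe, a 4-fold
cross-validation harness, the associated evaluation statistics, and a
synthetic nodule phantom generator that makes every stage testable on a
desktop CPU without any imaging data.

## Label model

Each attribute is ordinal: five levels for malignancy, margin, sphericity,
subtlety and texture; six for calcification, whose sixth level means
"absent". `binarize()` applies the standard two-level re-categorization:
levels 1–3 map to 0 and 4–5 to 1 for the five-level attributes (an
"indeterminate" malignancy is negative), while calcification maps levels
1–5 (any calcification present) to 0 and level 6 to 1. The mapping is
monotone in every ordinal input and reaches all 64 binary combinations;
both facts are verified by enumeration over all 18,750 ordinal
combinations in the test suite.

## Architectures

Both networks take one fixed-size cubic intensity patch per nodule and end
in six sigmoid heads: five semantic tasks plus malignancy.

* **HSCNN baseline** (`arch_config("hscnn")`): one shared 3D convolutional
  feature extractor feeds all five semantic heads.
* **HSNet** (`arch_config("hsnet")`): each semantic task has its own 3D
  extractor, one convolutional block deeper than the baseline, so each
  branch can learn features specific to its attribute.

A convolutional block is convolution (3×3×3, same padding) → batch
normalization → ReLU → channelwise dropout → max-pool (2, stride 2). After
the blocks, a dense layer produces the branch feature vector. The
malignancy head consumes the concatenation of the five branch feature
vectors and the five semantic probabilities, so its input width is
`5 * branch_feature_dim + 5`. Two structural decisions matter:

* **Tap point.** Branch features enter the fusion vector from the
  *activation output*, before dropout, so the malignancy head is never fed
  features with dropped units.
* **Interpretability contract.** Semantic probabilities are computed
  before, and independently of, the malignancy head; zeroing the fusion
  weights provably cannot change a semantic output (asserted in tests).
  The baseline is the same code path as HSNet with `shared_extractor =
  TRUE` and the shallower block count — there is no second implementation
  to drift.

The reference layer counts, filter widths and dense dimensions are not
dictated by the architecture concept, so every one is a configuration
field. The defaults (three blocks of 16/32/64 filters, 128-dim branch
features, 256-dim fusion hidden layer, dropout 0.3, 32³ patches) are sized
so that the default model builds and runs forward on a laptop; the
training demonstrations below use a slimmer instantiation.

Dense layers use a leaky rectifier (slope 0.01). Unlike the
batch-normalized convolutional blocks, a dense layer has no normalization
to re-center its pre-activations, and a fully dead rectified layer
silently reduces every head to its base rate — a failure mode we observed
at higher learning rates and eliminated by the leaky slope. Dropout inside
convolutional blocks is channelwise (whole feature maps are dropped per
sample), the standard form for convolutional activations; dense-layer
dropout is elementwise.

## Numerical engine

No deep-learning framework is available to R here, and the architecture
is the package's subject matter, so the network runs on a compact
compiled engine (`src/nnops.cpp`): 3D convolution as a per-sample
branch-free im2col unfold over a zero-padded copy of the volume followed
by a BLAS GEMM, with fused batch-norm + ReLU + dropout scaling, explicit
backward passes for every operation, and single-precision activations
(double-precision parameters and accumulated statistics at the R level).
The backward pass is validated against central finite differences on a
small double-checkable configuration in the development history and
against float-tolerance finite differences in the suite. Max-pooling uses
precomputed index plans; ties go to the first maximum. Batch-norm uses
batch statistics in training, running statistics (momentum 0.1) at
inference, and `eps = 1e-5`.

## Training recipe

`train_model()` implements the full recipe:

* **Loss.** Weighted sum of per-head binary cross-entropies (weights
  default to 1; probabilities clipped at 1e-7), averaged over the batch.
* **Optimizers.** SGD with momentum 0.9, Adam, RMSProp.
* **Cyclical learning rate.** The triangular policy with no amplitude
  decay: the rate rises linearly from `base_lr` to `max_lr` over
  `clr_step_size` iterations and falls back symmetrically; the default
  step is two epochs of iterations.
* **Stochastic weight averaging.** From `swa_start_epoch` (default
  `0.75 * epochs`) the end-of-epoch weights are folded into a running
  arithmetic mean, `w_swa <- (w_swa * n + w) / (n + 1)`; afterwards the
  batch-norm running statistics are recomputed over the training set with
  cumulative averaging (dropout disabled during this pass, so the returned
  model is deterministic). SWA averages are only meaningful once the
  trajectory oscillates around a basin; if averaging starts while the loss
  is still falling steeply the averaged model can trail the final epoch.
* **Early stopping.** With a validation set, the checkpoint with the
  highest validation malignancy accuracy is returned (the main-head
  criterion); with SWA enabled the SWA model takes precedence.
* **Augmentation.** `expand_training_set()` expands the training set by a
  factor (default 6: the original plus five distinct non-identity cube
  symmetries sampled without replacement from the 48-element group).
  Validation and test sets are never expanded; the cross-validation
  harness asserts this on every rotation.

All randomness (weight init, shuffling, dropout, augmentation choice,
fold assignment) flows from explicit integer seeds; a fixed seed on a
fixed platform reproduces histories exactly. Cross-platform bit equality
is not promised.

## The phantom generator

`phantom_config()` / `generate_samples()` render one synthetic nodule per
cubic volume over Gaussian background noise (mean −800, SD 50, HU-like
units). Each ordinal attribute controls one monotone voxel-level cue:

| attribute | render control | default per-level values |
|---|---|---|
| sphericity | largest/smallest semi-axis ratio of an oblate ellipsoid | 3.0, 2.2, 1.6, 1.25, 1.0 |
| margin | Gaussian boundary blur sigma (voxels) | 1.8, 1.4, 1.0, 0.7, 0.4 |
| subtlety | shell contrast over background | 100, 200, 300, 450, 600 |
| texture | absolute core density | −600, −450, −300, −150, 50 |
| calcification | hyperdense (800) inclusion pattern | popcorn, laminated, solid, non-central, central, absent |
| malignancy | radius fraction of grid half-width; spike amplitude/count | 0.24–0.36; 0–0.30 of radius, 0–10 spikes |

The nodule is two-zone: an inner core (normalized radius ≤ 0.55) at the
texture-controlled density and an outer shell at background + subtlety
contrast. Separating the two zones is deliberate: a single fill value of
`core_density + contrast` confounds texture with subtlety so strongly
that no single image statistic can recover subtlety reliably, defeating
the generator's purpose of providing a provably learnable task.
Calcifications are rendered after the boundary blur (with their own mild
0.5-voxel blur) so that a poorly defined margin cannot erase them.
Orientation is uniformly random; ±10% multiplicative jitter on every
continuous parameter makes adjacent levels overlap so the task is not
degenerate. Radius and spike tables are sized so the worst-case nodule
(largest radius, strongest anisotropy and spiculation, +10% jitter)
still fits a 16-voxel grid with margin; oversized custom configurations
raise a sizing error rather than clipping.

**What the phantom does and does not emulate.** It reproduces the
*semantics* of the attribute scales — monotone, partially confounded,
noisy voxel cues — not the appearance of lung CT: no vessels, pleural
attachment, respiratory artifacts, scanner spectra, or annotation noise.
Passing the learning demonstrations therefore shows the pipeline is
correct and the architecture can learn such cues, not that it attains any
particular performance on clinical data.

**Recoverability.** `phantom_statistics()` computes one intensity-only
statistic per attribute (moment anisotropy; ray-profile edge width; rim
contrast; centre-extrapolated core density; peak intensity; mask volume)
from a second-moment fit of the thresholded volume. At the default 32³
grid each statistic separates its binarized attribute with AUC > 0.8 on
200 samples — the property the training demonstrations rely on. This
recoverability degrades with resolution (at 16³ the core, rim and
calcification structure is sub-voxel), which motivates the 24³ size used
in the learning demonstration.

## Evaluation statistics

* Confusion matrices at threshold 0.5 with ties predicted positive (the
  threshold is a parameter; the tie rule is documented behaviour).
* ROC-AUC in the rank-based Mann–Whitney form with ties counted 0.5,
  tested against an exhaustive pair-counting oracle.
* `fold_summary()` reports both the sample SD (n−1) and population SD (n)
  conventions. Published fold tables in this literature use either;
  matching the printed comparison-table SDs requires the population
  convention, and the package always states which it reports.
* `paired_t()` — the paired-sample t test on per-fold AUC differences
  (df = n−1, two-sided p, 95% CI), delegated to `stats::t.test` and
  verified against the closed form.
* `ps_test()` — the two-classifier significance statistic
  Ps = |e1 − e2| / sqrt(q(1−q)(1/n1 + 1/n2)), q = (e1+e2)/2, with
  Ps ≥ 1.96 declaring a difference at 95% confidence. The denominator is
  the standard two-proportion form; with error rates e = 1 − mean AUC and
  equal fold sizes n1 = n2 = 1063 it reproduces published comparison
  values to three decimals (e.g. 7.717 for calcification, 19.182 for
  sphericity), which fixes the reading of the formula.

## Cross-validation harness

`make_folds()` shuffles then assigns cyclically (optionally stratified on
binarized malignancy — on by default, since small folds otherwise drift in
class balance; switch off for literal fidelity to unstratified splitting).
`plan_rotations()` fixes the standard four rotations (train 2+3 / val 4 /
test 1, and cyclic shifts); the validation fold is used only for
early-stopping checkpoint selection, never for gradient updates.
`run_crossval()` augments training folds only, asserts train/test id
disjointness on every rotation, aggregates per-label fold summaries, and
— when a baseline architecture is supplied — reports per-label paired t
tests on fold AUC differences and Ps statistics from mean-AUC error
rates.

## Problem sizes used in the checks

The package's own verification runs are sized for a single desktop CPU
core:

* statistic recoverability: 200 phantoms at the default 32³ grid;
* the learning demonstration: 600 training / 200 test phantoms at 24³,
  HSNet with filters (8, 16, 32), 64-dim branch features, 128-dim fusion
  hidden layer, dropout 0.1, SGD-CLR+SWA (base 5e-3, max 3e-2, two-epoch
  half-cycle), batch 16, with the shared-extractor baseline trained on
  identical data and seeds for the malignancy comparison;
* cross-validation integration tests: 30–48 phantoms at 16³ with
  deliberately tiny networks, checking plumbing rather than accuracy.

These sizes are the package's desk-scale choices; nothing about the
methods is specific to them.

## Known limitations

* The engine is a compact CPU trainer: single-threaded, single-precision
  activations, no convolution algorithm selection; it is sized for
  patches up to ~32³, not for clinical-scale throughput. From-scratch SGD
  at these batch counts needs several hundred iterations before
  shape-sensitive attributes (sphericity in particular) start to move;
  the adaptive optimizers converge noticeably faster on the phantom task.
* Ordinal levels are taken as given, one per nodule; reconciling multiple
  annotators is upstream of this package.
* The phantom's uniform level priors are a deliberate simplification;
  real cohorts are imbalanced (configurable via `level_probs`).
* DICOM ingestion and nodule cropping are out of scope; volumes enter as
  NIfTI patches with one nodule each.
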