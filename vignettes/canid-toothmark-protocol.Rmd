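---
title: "Discriminating canid tooth marks: models, protocol and design notes"
author: "canidmarks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discriminating canid tooth marks: models, protocol and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canidmarks)
```

## The problem

When livestock is killed and scavengers strip the carcass, the tooth marks
left on long-bone shafts are often the only physical evidence of which
predator was responsible. Wolves, domestic dogs and foxes all leave two mark
types: roughly circular *pits* and elongated, U-sectioned *scores*.
`canidmarks` implements a hybrid geometric-morphometric and machine-learning
protocol that discriminates the three canids from landmark models of those
marks: a 7-landmark 2D model of score cross-sections and a 17-landmark 3D
model of whole pits.

Four data views are analysed in parallel:

1. seven cross-section measurements of scores, including the opening angle
   (OA);
2. the same measurements excluding OA;
3. shape-space principal component scores of the GPA-aligned score
   cross-sections;
4. form-space principal component scores of the GPA-aligned pits.

Each view is tested for group differences with pairwise MANOVA and fed to an
RBF-kernel support vector machine under a bootstrap / split / cross-validated
random-search protocol.

## The synthetic reference sample

The package is fully self-contained: `simulate_reference_sample()` generates
a three-class landmark sample with the structure the analyses assume, at the
study's sample sizes (pits: fox 29, wolf 24, dog 30; scores: fox 41, wolf 30,
dog 34).

Class templates are parametric mark profiles — a parabolic groove
cross-section for scores and an elliptical parabolic crater for pits — and
class signal is placed in three channels at once so every view carries
discriminative information:

* **size**: overall mark width, default wolf 3.0 mm > dog 2.0 mm >
  fox 1.2 mm, matching the ordering visible in metric ordinations of real
  marks and the relative cuspid sizes of the animals;
* **relative depth**: maximal depth as a fraction of width, default fox 0.55
  > dog 0.40 > wolf 0.25 — foxes leave the deepest, wolves the most
  superficial marks;
* **dispersion**: per-landmark Gaussian noise as a fraction of centroid size,
  default wolf 0.020 > dog 0.015 > fox 0.010, reproducing the observation
  that wolves are the most and foxes the least variable class.

Per-specimen log-normal size jitter (sd 0.1 on the log scale) keeps sizes
positive and overlapping realistically. The `separation` parameter
interpolates the per-class size and depth values between their common
geometric mean (`separation = 0`, all templates identical — the null
generator used to verify that no label signal leaks through the pipeline)
and beyond the stated values. Its default, 2.0, is the one deliberately
calibrated constant in the generator: it is set so that the full protocol
reaches the perfect held-out classification that the original study reports
on its real scans. That calibration *mirrors* the study's empirical
separability rather than proving it: passing tests on this generator show
the pipeline is correct and leak-free, not that real wolf, dog and fox marks
are this cleanly separated.

What the generator deliberately does **not** emulate: anisotropic or
correlated landmark noise (digitising error on real scans is certainly
structured), within-class multimodality (tooth position, prey bone density),
scanner artefacts, and any covariance between size and shape beyond the
depth-ratio construction. Conclusions about real assemblages still require
real reference data.

## Morphometric machinery

**Centroid size** is the standard measure, `sqrt(sum((x - centroid)^2))`, in
the input units (millimetres by convention).

**GPA.** `gpa()` centres and scales every configuration to unit centroid
size, then alternates optimal rotation onto the consensus with consensus
re-estimation until the consensus changes by less than `tol` (default 1e-10,
maximum 100 iterations; non-convergence is an error, and the residual trace
is monotone by construction). Rotations are proper only — tooth marks are
chiral, so reflections are never allowed. Two post-processing steps matter:

* *Canonical orientation.* The converged sample is rotated so the consensus
  lies on its principal axes with a deterministic sign convention (restricted
  to proper rotations). Without this the output orientation would inherit the
  arbitrary orientation of the first specimen; with it, aligned coordinates
  are invariant to any similarity transform of the input, to machine
  precision.
* *Tangent projection.* The aligned, unit-size configurations live on a
  sphere; `gpa()` also returns their orthogonal projection onto the tangent
  space at the consensus (`$tangent`), which is the input for linear
  statistics. The projection matters for dimension bookkeeping: centring,
  rotation optimality and the projection are all *linear* constraints, so
  shape data have exactly `kd - d - d(d-1)/2 - 1` informative components
  (10 for 7x2 scores, 44 for 17x3 pits), whereas the unprojected sphere
  constraint is nonlinear and would smear variance into one extra component.

**Form space.** `to_form_space()` multiplies each specimen's aligned
coordinates by the natural logarithm of its centroid size, keeping all `kd`
coordinate columns (14 for scores, 51 for pits with n = 83). The published
form-space dimensionalities are reproduced only under this convention, which
is why it was chosen over the common alternative of appending ln(CS) as one
extra column; the construction is isolated in a single function so the
alternative is a one-line swap. Because ln(CS) must be positive, coordinates
are interpreted in micrometres for the protocol (`units = 1000` for
millimetre input); the function refuses centroid sizes at or below 1.

**Thin-plate splines.** `tps_warp()` uses the kernel `r^2 log(r^2)` in 2D
and `-r` in 3D, maps reference landmarks exactly onto targets, reports the
bending energy of the non-affine part, and underlies the PC-extreme
deformation grids (`pc_extreme_shapes()` reconstructs the configurations at
the observed extremes of a component).

**Cross-section measurements.** The seven groove descriptors (WIS, WIM, WIB,
D, OA, LWA, RWA) operationalise "thickness, depth and various angles" from
the landmark roles: widths at the surface, half depth and three-quarter
depth, perpendicular depth from the deepest landmark to the surface chord,
the opening angle at the deepest point, and the two wall angles. Their exact
historical definitions trace to earlier cut-mark work whose supplementary
illustrations are not reproducible here, so the formulas are this package's
explicit operationalisation, centralised in `compute_measurements()` where a
substitution is a one-line change. All seven are rigid-motion invariant;
lengths scale and angles are fixed under uniform scaling.

## Statistics

**PCA** (`gm_pca()`) is plain covariance PCA via SVD, keeping
`min(n - 1, p)` score columns. `count_pc_scores()` implements the two
counting conventions described above.

**MANOVA** (`manova_pairwise()`) compares two classes on PC scores. Because
44-51-dimensional responses with 24-41 specimens per group are unworkable
directly, scores are truncated to the leading components explaining 95% of
cumulative variance, capped at `n_a + n_b - 3` columns. Box's M (chi-square
approximation, alpha = 0.05) gates the statistic: Hotelling-Lawley for
homogeneous groups, Wilks' Lambda otherwise; in the two-group case both
reduce to Hotelling's T-squared and their F approximations are exact, so the
gate never changes a two-group p-value, only the reported statistic's name.
Under a simulated null the test's type-I error is calibrated (checked at
1000 replicates in the test suite). Which scores the original analysis fed
to MANOVA is not recoverable from its text; the truncation rule is this
package's declared choice.

## The classification protocol

The protocol in `run_protocol()` follows the published recipe: stratified
bootstrap augmentation to 1000 rows, a stratified 70:30 train/test split,
50 iterations of random search over cost and gamma sampled log-uniformly
from [1e-2, 1e3] (wide enough to contain typical optima for both metric and
PC-score inputs), each candidate scored by 10-fold cross-validated balanced
accuracy, and a final RBF SVM (one-vs-one multiclass) evaluated on the
held-out specimens.

Three choices deserve justification:

* **Split before bootstrap.** The literal published order (bootstrap, then
  split) duplicates specimens across the train/test boundary and inflates
  test accuracy; it is available as `paper_order = TRUE` for comparison, but
  the default splits first and augments only the training partition, so
  every reported test metric refers to genuinely unseen specimens.
* **Specimen-grouped CV folds.** Cross-validation on bootstrap-duplicated
  rows is itself leaky: a memorising configuration (very large gamma and
  cost) classifies duplicates of its own training rows perfectly and wins
  the search while generalising at chance. Fold assignment is therefore done
  at the level of originating specimens (the bootstrap records row origins),
  which restores the search's ability to rank configurations.
* **Per-view feature scaling.** The measurement views mix units (mm and
  degrees) and are standardised inside each SVM fit, the libsvm convention.
  PC-score views are *not* standardised: their trailing components have
  near-zero variance by construction, and standardising them would amplify
  pure noise into the kernel.

Evaluation (`classification_metrics()`) reports the confusion matrix in
fixed alphabetical label order (dog = 0, fox = 1, wolf = 2), Cohen's kappa,
macro sensitivity and specificity, balanced accuracy, the exact
Clopper-Pearson 95% interval on the proportion correct, and the global mean
squared error of the integer-coded local errors E = i - x. The label
encoding is this package's convention; a squared-error loss on labels is
only defined given one. Note that this loss is exactly 0 for a perfectly
classified test set — published tables that pair perfect accuracy with a
small positive MSE cannot be reproduced by this definition, and the package
reports the faithful value. Training-time microbenchmarks (200 repetitions,
mean milliseconds) are available via `benchmark = TRUE` but are
hardware-dependent and never compared against published timings.

## Reproducibility and problem sizes

Every stochastic stage derives its seed from the single `protocol_config()`
seed, so identical configurations give byte-identical JSON reports. The full
four-view protocol at default sizes (bootstrap 1000, 50 search iterations,
10 folds) runs in roughly two minutes on one CPU core. The test suite
exercises the full-size protocol once; orchestration and null-calibration
tests use reduced sizes (bootstrap 200, 4-8 search iterations, 5 folds) and
the chance-level check averages balanced accuracy over 20 seeds of the
separation-zero, equal-noise generator, expecting 1/3 within Monte-Carlo
error.

## Known limitations

* The generator's isotropic noise and parametric templates are stand-ins for
  unknown real within-class covariance; perfect synthetic classification
  validates the pipeline, not field performance.
* Landmark roles (which index is the deepest point, etc.) are enforced
  conventions; files digitised under other schemes must be reordered before
  measurement.
* No sliding semi-landmarks, missing-landmark estimation, or
  reflection-invariant matching; pits have no measurement model (they are
  analysed morphometrically only).
* Real-data p-values, optimal hyperparameters and training times from the
  original study depend on the original scans and hardware and are
  reproduced structurally, not numerically.
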