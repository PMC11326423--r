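---
title: "Automatic IHI rating: models, statistics and the phantom testbed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automatic IHI rating: models, statistics and the phantom testbed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Incomplete hippocampal inversion (IHI) is an atypical folding pattern of the
hippocampus — a rounder, more vertical, more medially positioned hippocampal
body with deeper neighbouring sulci — present in roughly 15–20% of the
general population, more often on the left than on the right. It is rated
visually on coronal T1 slices with four ordinal criteria:

* **C1** — verticality and roundness of the hippocampal body,
* **C2** — verticality and depth of the collateral sulcus,
* **C3** — medial position of the hippocampus,
* **C5** — sulci of the fusiform gyrus exceeding the subiculum level.

C1–C3 are scored 0–2 in steps of 0.5, C5 in steps of 1. (A historical
criterion C4, subiculum bulging, is excluded: it is nearly constant in the
population and unreliable to rate; `ihiscore` does not represent it.) The
composite IHI score is the plain sum of the four criteria (0–8), and a
hemisphere is classified as showing IHI when the composite is at least 4.
Because visual rating is slow, `ihiscore` automates it: one regression model
per criterion predicts a continuous score from a grey-matter crop around the
hippocampus, predictions are rounded onto the rating grids, and the rounded
criteria are summed. Keeping the per-criterion structure — rather than
regressing the composite directly — keeps the automatic score interpretable
criterion by criterion.

Rounding happens **before** summation, and exact grid midpoints round *up*.
The tie direction is a deliberate bias toward detecting IHI rather than
missing borderline cases; it is deterministic and affects only
measure-zero inputs.

## Inputs and preprocessing

The package consumes spatially normalized grey-matter probability maps
(NIfTI). Tissue segmentation and normalization to template space are
upstream and out of scope. The hippocampal region of interest is expressed
as half-open voxel-index slices on the template grid; the default box
`[24,96) x [54,107) x [16,49)` yields 72 x 53 x 33 crops covering both
hippocampi and the surrounding sulci. The printed slice notation is
interpreted as 0-based half-open voxel indices (slice syntax); the box is a
configuration value (`roi_box()`), so any other convention is a one-line
change.

Right-hemisphere crops are mirrored across the left-right axis into the
left-hemisphere frame before modelling (`mirror_hemisphere()`): one
geometric frame per model, with the hemisphere kept as metadata. Intensity
normalization (`normalize_intensity()`) is per-crop min-max; grey-matter
maps are already near-[0,1], and a constant (contrast-free) crop maps to
zeros rather than erroring.

## Split protocol

Per cohort, 25% of subjects are isolated as a test set; the remainder is
split 80/20 into training and validation, with floor rounding at each stage
(`split_sizes()`; e.g. 2008 → 1205/301/502). Splits are searched, not
drawn once: `select_stratified_split()` draws 200 candidate partitions
(configurable) and keeps the one minimizing distributional discrepancy
between train∪validation and test across all stratification variables —
the four criteria plus age, weight, height, sex, handedness and centre.
Numeric variables are compared with the two-sample Kolmogorov–Smirnov
statistic; categorical ones with total-variation distance, which lives on
the same [0,1] scale (a two-sample KS statistic is not meaningful for
unordered categories). The aggregate over variables is the **maximum**
(worst variable) by default — the conservative reading — with a mean
switch. The same selection rule is then re-applied to the non-test
remainder to pick the validation subset. Ties in the candidate stream break
toward the lowest candidate index, so the search is fully reproducible.

Multi-cohort training strategies (`assemble_strategy()`) pool the train and
validation subsets of the chosen cohorts; every cohort's test subset is
preserved untouched, and a leakage assertion (train ∩ test = ∅) runs on
every assembled experiment.

## Models

Three deep families share one train/predict contract:

* **conv5-FC3** — five blocks of conv(3³)–batch-norm–ReLU–max-pool(2),
  then three fully connected layers to a scalar;
* **resnet3d** — five residual blocks (conv–bn–ReLU–conv–bn plus identity
  shortcut, 1³ projection when channels change) separated by max pooling,
  head FC–ReLU–dropout(0.5)–FC;
* **secnn** — resnet3d with a squeeze-and-excite gate per block (global
  average pool per channel → FC(reduction) → ReLU → FC → sigmoid →
  channelwise rescale).

Pooling uses size-2 windows with floor semantics and axes of extent 1 stop
shrinking; on the full 72 x 53 x 33 ROI the five pools leave 2 x 1 x 1.
Training minimizes mean squared error on the raw (un-rounded) criterion
labels with Adam (learning rate 1e-4, weight decay 1e-4, batch 16, at most
50 epochs, early-stopping tolerance 0 — i.e. training runs all epochs and
the epoch with the lowest validation loss supplies the weights). These
defaults are the reference regime; the phantom experiments use a
scaled-down preset (below). Channel widths and FC sizes are configuration,
not code: the defaults are 8-16-32-64-128 channels with FC 1024-64-1, and
the reduced presets used in tests are 4-8-16-16-32 with FC 64-16-1.
The squeeze-excite reduction ratio defaults to 4 so that it never exceeds
the first block's channel count (the builder rejects ratios above the
smallest width). One network is trained per criterion and hemisphere frame;
the composite is never a regression target.

The layers are implemented in the package itself (im2col + GEMM Rcpp
kernels for 3D convolution and pooling, vectorized R elsewhere), with every
gradient verified against central finite differences. Determinism is part
of the contract: builders and the training loop are pure functions of their
seeds, and a retrained run reproduces `best_val_loss` exactly.

**Ridge baseline.** Flattened crops feed a ridge regression fitted in
closed form through the dual (kernel) formulation — exact for p ≫ n — with
the penalty chosen on a fixed log-spaced grid (1e-3…1e9) by nested
cross-validation (5 outer × 6 inner folds). Outer-fold predictions are
retained for honest performance estimates; the final model refits on all
data with the penalty selected by a full inner-style CV.

**Saliency.** `saliency_group_map()` backpropagates the scalar output to
the input voxels in eval mode, averages |gradient| over the supplied crops,
and retains exactly the 1000 largest voxels (ties broken by voxel order).
For the linear ridge model the gradient is the coefficient vector, so its
saliency is the |coefficient| map — the two routes coincide analytically.

## Agreement statistics

Composite scores are nearly continuous, so predicted-vs-manual agreement is
measured with the intraclass correlation. The default variant is
**ICC(2,1)** — two-way random effects, single rater, absolute agreement —
because the use case is inter-rater-style reliability of single ratings and
systematic offsets between an automatic rater and a human should count as
disagreement; ICC(3,1) (consistency) is a switch and is recorded in every
report. Individual criteria use Cohen's kappa over the *declared* category
grid (so categories unobserved in a sample still weight correctly):
quadratically weighted for the ordinal C1–C3, unweighted for C5, whose
categories are not treated as equally spaced. Kappa refuses off-grid
values: predictions must be rounded first, by construction.

Uncertainty comes from a subject-level bootstrap (100 replicates by
default): replicate SD is the SE, and the 95% CI is the percentile interval
(normal approximation available). Two methods are compared by computing the
metric difference on the *same* resampled index sets — the replicate index
matrices are bitwise identical by construction and asserted in tests —
yielding t = mean(d)/sd(d) with n_boot − 1 degrees of freedom and a
Bonferroni correction over the declared family of simultaneous tests. Note
the denominator is the bootstrap SE of the difference (the replicate SD),
*not* SD/√B: the replicates are not independent observations, and the
SD/√B reading would inflate the statistic roughly tenfold. Under a
simulated null this choice is calibrated (rejection rate ≈ 5%), which the
acceptance suite checks over 500 simulated datasets.

## The phantom testbed

The real cohorts behind this kind of study are restricted, so the package
ships a synthetic hippocampus phantom that makes every downstream stage
testable. A crop is built from an ellipsoidal "hippocampal body" over a
cortical plate, with four latents in [0,1] mapped monotonically to the
criteria: t1 rotates the body from horizontal to vertical (and fattens its
short axis — roundness); t2 deepens a dark collateral-sulcus wedge rising
from below; t3 translates the body medially; t5 deepens a second, medial
fusiform groove. Latent ℓ maps to truth score `round_prediction(2ℓ)`. The
geometry is deliberately simple: the goal is a monotone, learnable
latent-to-image map with known ground truth, not anatomical realism —
passing tests show the pipeline recovers a known signal under controlled
nuisance, not that it reaches any particular accuracy on real MRI.

Beyond the latents, the generator models what real normalized maps actually
exhibit, each dial chosen once at a realistic level:

* **acquisition differences per cohort** — Gaussian voxel noise, blur FWHM
  and a contrast factor (the default four-cohort experiment varies all
  three);
* **residual misregistration** — a per-subject random translation of the
  whole anatomy (SD 0.03 of the box, roughly one voxel), because spatial
  normalization is never perfect;
* **anatomical nuisance** — per-subject body size, amplitude, elongation
  and plate thickness/position variation;
* **rater noise** — each criterion flips one grid step with probability
  0.65, calibrated by sweep so that truth-vs-observed composite ICC at
  n = 500 falls in the 0.70–0.85 band reported for expert inter-rater
  reliability (the phantom's strong bimodal signal makes composite ICC
  insensitive to single-step flips, hence the seemingly high probability);
* **prevalence control** — latents are drawn from a bimodal mixture of a
  "typical" Beta(1.3, 6.5) near 0 and an "IHI" Beta(6.5, 1.6) near 1, with
  the subject-level mixture weight solved *exactly* (convolution of the
  per-criterion score pmfs) so the expected fraction of hemispheres with
  composite ≥ 4 hits the target — 20% left, 8% right by default, mirroring
  the population asymmetry.

All generation is a pure function of (spec, seed); per-subject seeds derive
from the master seed by a counter, never from global state.

### The angle-driven nonlinear benchmark

With amplitude-coded grooves, every voxel's intensity is monotone in the
depth latents, and a fixed-voxel linear model is then nearly optimal — on
the standard composite phantom the ridge baseline is in fact the stronger
method. That is a property of simple phantom geometry, not of the models.
The regime where convolutional models are genuinely required is configural:
`angle_phantom_dataset()` varies only the body's in-plane angle (roundness
confound disabled, so the score depends on the angle rather than any
mean-intensity cue) under per-subject anatomy nuisance and misregistration
jitter. On this benchmark conv5-FC3 reaches held-out ICC ≈ 0.8–0.9 while
ridge degrades to ≈ 0.4–0.6, reproducing qualitatively the deep-vs-linear
ordering reported on real data.

## Problem sizes and numerical choices

The phantom experiments in the test and acceptance suites run at reduced
scale, chosen as the package's own benchmark sizes: 24 x 20 x 16 crops,
400-subject cohorts split 240/60/100, reduced-width nets
(4-8-16-16-32 / FC 64-16), learning rate 1e-3 and 20 epochs — small enough
for a single CPU, large enough that composite ICC ≥ 0.8 is recovered with
margin. Full-size defaults (72 x 53 x 33, 8-16-32-64-128, lr 1e-4,
50 epochs) remain the package defaults for real use.

Other numerical decisions: batch-norm uses ε = 1e-5 and momentum 0.1, with
running statistics snapshotted together with the best-epoch weights;
weight decay enters Adam through the gradient (the conventional
non-decoupled form); degenerate inputs error early and informatively
(constant labels for ridge, zero-variance ICC, single-category kappa,
non-finite losses); the KS statistic is computed directly from the ECDFs
because rating data are tie-rich and only the statistic, never the p-value,
enters split selection.

## Known limitations

The phantom's geometry is four-parameter and its nuisance model is
Gaussian; real grey-matter maps carry segmentation artefacts, cohort-level
rater drift, age effects on anatomy and genuinely non-ellipsoidal shape
variation, none of which are modelled. Accuracy numbers on the phantom
therefore say nothing quantitative about real MRI. The C5 scale is encoded
as {0, 1, 2} (a 2-point scale in steps of 1); the alternative 0–1 reading
exists in the field and is a one-line change in `criterion_grid()`. The
ridge-vs-CNN ordering is benchmark-dependent by design: on amplitude-coded
signals the linear model wins, and reports should state which regime they
refer to.
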