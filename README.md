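# ihiscore

Automatic rating of **incomplete hippocampal inversion (IHI)** from
spatially normalized grey-matter probability maps.

IHI is an atypical folding pattern of the hippocampus — a rounder, more
vertical, more medially positioned hippocampal body with deeper
neighbouring sulci — found in roughly 15–20% of the general population,
more often in the left hemisphere than in the right. It is normally rated
visually on coronal T1 slices, which does not scale to modern cohorts.
`ihiscore` automates the rating protocol for researchers running
population-scale neuroimaging studies.

## What it computes

Four ordinal criteria are predicted independently from a 3D grey-matter
crop around the hippocampus:

| criterion | anatomy | scale |
|---|---|---|
| C1 | verticality / roundness of the hippocampal body | 0–2, step 0.5 |
| C2 | verticality and depth of the collateral sulcus | 0–2, step 0.5 |
| C3 | medial position of the hippocampus | 0–2, step 0.5 |
| C5 | fusiform-gyrus sulci exceeding the subiculum level | 0–2, step 1 |

Each regressor's continuous output is rounded to its rating grid
(midpoints round up), and the composite IHI score is the sum

> S = C1 + C2 + C3 + C5 ∈ [0, 8],  IHI ⇔ S ≥ 4.

Predicting criteria and summing — rather than regressing S directly —
keeps the automatic score interpretable criterion by criterion. The
historical criterion C4 (subiculum bulging) is excluded from the protocol
and is not representable in the package.

The package provides, as separate composable modules:

* **ratings_core** — grids, rounding, composite, IHI classification, TSV
  rating-table I/O;
* **preprocess** — NIfTI loading, the template-space hippocampal ROI crop
  (`[24,96) × [54,107) × [16,49)`, i.e. 72 × 53 × 33 voxels), hemisphere
  mirroring, intensity normalization, flattening;
* **phantom** — a synthetic hippocampus generator with known ground-truth
  criteria, cohort effects (noise/blur/contrast/prevalence), anatomical
  nuisance, misregistration jitter and calibrated rater noise, so the whole
  pipeline is testable without restricted data;
* **splitting** — the stratified split search (25% test, 80/20
  train/validation of the remainder, 200 candidates scored by
  Kolmogorov–Smirnov / total-variation discrepancy, worst variable
  minimized);
* **models** — three 3D CNN regressors (conv5-FC3, ResNet3d, SECNN) with
  their training loop (MSE, Adam, best-validation-epoch selection),
  a closed-form ridge baseline with 5 × 6 nested cross-validation, and
  gradient-backpropagation group saliency maps (top-1000 voxels);
* **evaluation** — ICC(2,1)/ICC(3,1), quadratically weighted and unweighted
  Cohen's kappa, subject-level bootstrap CIs, paired-bootstrap Student's
  t-tests between methods with Bonferroni correction;
* **experiments** — end-to-end orchestration of multi-cohort training
  strategies at phantom scale.

The CNNs, backprop and Adam are implemented in the package itself (Rcpp
im2col/GEMM kernels + vectorized R), with every gradient verified against
finite differences in the test suite.

## Worked example

Generate a phantom cohort, search a stratified split, train a conv5-FC3 for
the collateral-sulcus criterion and measure held-out agreement:

```r
library(ihiscore)

spec <- cohort_spec("demo", 120, grid_shape = c(24L, 20L, 16L),
                    noise_sd = 0.02, blur_fwhm = 1.0, rater_flip_prob = 0.05)
cohort <- generate_cohort(spec, seed = 7)
cohort
#> phantom cohort 'demo': 120 subjects, grid 24x20x16, IHI prevalence L 21.7% / R 10.0%

recs <- cohort$ratings_observed[cohort$ratings_observed$hemisphere == "left", ]
assignment <- select_stratified_split(recs, split_config(n_candidates = 50, seed = 7))
table(assignment$set)
#>       test      train validation
#>         30         72         18
attr(assignment, "badness")$aggregate
#> [1] 0.1555556

ids <- function(s) assignment$subject_id[assignment$set == s]
crops <- cohort$crops$left
names(crops) <- sapply(crops, attr, "subject_id")
y <- function(id) recs$c2[match(id, recs$subject_id)]

net <- build_conv5fc3(c(24L, 20L, 16L), channels = c(4L, 8L, 16L, 16L, 32L),
                      fc_widths = c(64L, 16L))
fit <- train_regressor(net, crops[ids("train")], y(ids("train")),
                       crops[ids("validation")], y(ids("validation")),
                       train_config(learning_rate = 1e-3, max_epochs = 12, seed = 7),
                       criterion = "C2", hemisphere = "left")
fit
#> conv5fc3 regressor (criterion C2, hemisphere left, strategy NA): best epoch 12, val MSE 0.1732

pred <- round_prediction(predict_criterion(fit, crops[ids("test")]), "C2")
bootstrap_metric(function(a, b) cohen_kappa(a, b, "quadratic", criterion_grid("C2")),
                 y(ids("test")), pred, n_boot = 100, seed = 7)
#> metric 0.6638 (bootstrap mean 0.6126, SE 0.1766, 95% CI [0.1104, 0.8063], n = 30, B = 100)
```

The cohort's truth prevalence lands on the 20%/8% left/right targets; the
split search reduces the worst covariate discrepancy to 0.16 on a
30-subject test set; after 12 short epochs the network reaches a held-out
quadratic kappa of 0.66 against the simulated rater (the small test set
makes the bootstrap CI wide — full-scale runs use 50 epochs and hundreds of
test subjects). Composite scoring then sums the four rounded criteria and
`classify_ihi()` applies the ≥ 4 rule.

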