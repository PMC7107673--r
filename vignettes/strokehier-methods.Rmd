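---
title: "Hierarchical LVO triage: models, synthetic data and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical LVO triage: models, synthetic data and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`strokehier` implements a three-tier evaluation system for large vessel
occlusion (LVO) in acute ischemic stroke. This vignette explains the model,
the synthetic data that stand in for patient records, and the design
decisions taken where the problem was genuinely open. It states no
empirical result beyond what the test suite and `scripts/acceptance.R`
themselves compute.

## The hierarchical model

LVO prediction is posed as binary classification at three nested feature
levels that mirror the escalating information available along the stroke
pathway: Level 1 (demographics and observable deficits), Level 2 (adding
clinical history, blood pressure, GCS and subscales), and Level 3 (adding
ten deep NCCT features). Four learner families are fitted per level:

- **Stepwise logistic regression** — bidirectional selection on Wald
  p-values with entry at p < 0.05 and removal at p > 0.10. A term removed
  in a sweep may not immediately re-enter in the same sweep, which
  prevents add/remove cycling; a repeated-selection-set check is a second
  guard. Perfect separation falls back to a ridge-penalized refit of the
  selected terms (with a warning) so predictions stay bounded.
- **Random forest** — 500 trees, √p candidate predictors per split,
  probabilities as averaged votes, Gini impurity importances.
- **RBF-SVM** — fitted on the variables the gradient-boosting model found
  useful (all with positive total gain; the family has no intrinsic
  selection), with cost and kernel width chosen by an internal 5-fold grid
  and Platt-type probability calibration.
- **Gradient boosting** — 300 rounds, depth 4, learning rate 0.1, early
  stopping on an internal stratified fifth of the training rows; consumes
  the raw table and learns default split directions for missing values.

Missing data policy: missing categorical cells become a literal `"Unknown"`
level (missingness in clinical data is often informative — an unrecorded
smoking status is itself a signal); missing continuous cells are imputed by
the median of the k = 5 nearest training neighbours, with distances taken
over the jointly observed standardized continuous features and scaled by
the number of shared features so rows with different missingness patterns
remain comparable. The imputation state is frozen on the training split and
applied unchanged to any future row, making it deployable. Gradient
boosting alone skips imputation. k = 5 and the distance scaling are package
choices; only the median-of-neighbours rule itself is fixed by the method.

Cutoffs: every model's probability threshold maximizes the empirical Youden
index γ = sensitivity + specificity − 1 over pooled out-of-fold predictions
from a stratified 10-fold cross-validation of the training split (the model,
its imputation state, its variable selection are refitted within each
fold). Pooling the folds, rather than averaging per-fold cutoffs, matches
the fact that one cutoff is reported per model. Score ≥ cutoff counts as
positive, and ties in the Youden scan resolve to the smallest candidate —
both boundary conventions are arbitrary but must be fixed for
reproducibility.

## The segmentation network and feature extractor

The hyperdense MCA sign — a bright intravascular clot dot — is segmented by
a U-Net-style encoder–decoder FCN: 3×3 convolutions (stride 1, same
padding), ReLU activations, 2×2 max pooling, channels doubling per stage,
nearest-neighbour upsampling with encoder skip connections, and a 1×1
convolution + sigmoid pixel head. At the full-scale profile (input 128×128,
depth 5, base 32) the bottleneck holds 1024 maps of 4×4; a global max pool
over them yields the 1024-feature patient vector. The exact channel
schedule between input and bottleneck is underdetermined by the reference
design; a doubling schedule ending in a wide bottleneck convolution is
assumed.

Training uses Adam (first-moment decay 0.9 — the stated "momentum"), the
Tversky loss `1 − (TP + ε)/(TP + α·FP + β·FN + ε)` with soft counts, and
hard-negative mining. Defaults α = 0.3, β = 0.7 penalize missed lesion
pixels harder, the recommended regime for very small lesions; at
α = β = 0.5 the loss reduces exactly to soft Dice (a test pins this
identity). Mining operates at epoch level: each epoch every patch's loss is
computed, all lesion-positive patches are kept plus the 3× hardest
negatives, and the retained pool is drawn into class-balanced minibatches
of 16 (half lesion-positive, cycled when positives are scarce) so every
optimization step carries foreground gradient. Two further stabilizers
guard against the all-background collapse a small lesion prior invites:
the weights with the best positive-patch loss are checkpointed and
returned, and a saturating positive-patch loss triggers a rollback to the
checkpoint with a halved step size. The
reference configuration (200 epochs, learning rate 1e-5) is preserved in
`segTrainConfig` documentation, but desk-scale runs default to fewer epochs
at a larger step; profiles are explicit configuration, not hidden behavior.

Per-patient extraction: all 12 patches are segmented; the slice with the
largest predicted area (binarized at 0.5, summed over both hemispheres) is
the representative slice, with the middle (third) candidate slice used when
nothing is predicted and ties broken to the earliest slice. Both hemisphere
patches of that slice pass through the feature head and the per-channel
elementwise maximum of the two is returned. Whether the extractor should see one
hemisphere patch, both patches, or the whole uncropped slice is
underdetermined; the two-patch maximum was chosen because it preserves
the strongest evidence from either side and makes the vector invariant to
which hemisphere carries the lesion (a property the suite tests by swapping
hemispheres). The network is implemented in vectorized R: each 3×3
convolution is one BLAS product against a C++-built im2col matrix, with the
exact adjoint in the backward pass; gradients are verified against finite
differences in development and the whole computation is single-threaded
deterministic given a seed (patches are canonicalized by name before the
seeded shuffle, so caller ordering is irrelevant).

The ten Level-3 features are chosen by per-channel two-sample pooled
Student t-tests (Welch behind a flag) on **training patients only**; the
selected indices are frozen and applied to test patients. Whether the
original analysis screened on all patients or training-only is not stated;
training-only prevents leakage and is the defensible default.

## NCCT preprocessing

Four steps convert a head volume into 12 patches of 128×128:

1. **Brain extraction** — below-skull-threshold voxels (default > 100 is
   bone) are labeled per slice; components touching the image border
   (exterior air) are discarded; the largest remaining component, after
   morphological closing (radius 2), is the brain. Skull voxels are never
   included.
2. **Rigid registration** — one in-plane transform for the whole volume:
   the brain centroid is translated to the image centre and the rotation is
   chosen by grid search (±15°, step 0.5°) with local refinement,
   maximizing the correlation between the middle candidate slice and its
   mirror across the mid-axis. The published pipeline names its
   registration tool but not its objective; bilateral symmetry is the
   stated goal, so it is optimized directly. If the optimized transform
   does not improve the symmetry score the identity is used (already
   aligned volumes legitimately optimize to ~identity). Whether
   registration is slice-wise or volume-wise is not stated; a single shared
   2-D transform was chosen and is the only variant implemented.
3. **Median filter + windowing** — an exact per-slice 3×3 median (C++
   selection network; larger odd kernels fall back to an ordered-statistic
   reference), then every voxel outside [20, 80] is set to 0 and voxels
   inside are unchanged. Zeroing rather than clipping follows the
   "thresholding" wording and the goal of suppressing skull and CSF;
   windowing is idempotent.
4. **ROI cropping** — two mirror-image 128×128 boxes (`[128:256, 212:340]`
   and `[256:384, 212:340]` in 0-based half-open (row, col) coordinates)
   over six candidate slices. The reference description of the slice range
   (4th through 10th) conflicts with its own six-slices-per-patient and
   12-patch counts; six slices (1-based 4–9 inclusive) are used because
   6 × 2 boxes = 12 patches.

## The synthetic cohort

`generateCohort()` draws the LVO label at 43.3% prevalence, then each
variable from its class-conditional marginal (130 LVO / 170 non-LVO
reference counts). Continuous variables are class-conditional normals with
published means and SDs back-solved from the printed 95% CIs at the
observed counts — only means and CIs are printed, so the CI back-solve is
the only dispersion information available. Structurally linked variables
are drawn as blocks so records are internally consistent:

- limb and facial weakness as a both/left/right/none side pattern whose
  margins reproduce the published any-side and per-side counts (the limb
  side counts overlap by exactly 3 resp. 7 bilateral cases; facial "yes"
  splits exactly into one side);
- smoking as a never/current/ex trichotomy with a shared Unknown mask;
- GCS subscales drawn first (discretized truncated normals in their 1–4 /
  1–5 / 1–6 ranges) with the total as their sum, and a two-stage
  missingness mask reproducing both the subscale and the total NA rates;
- systolic/diastolic pressure jointly missing.

The published summary prints a female percentage (58.5%) inconsistent with
its own counts (76/170 = 44.7%), and a sign-given-LVO percentage (97.1%)
inconsistent with 68/74 = 91.9%; the generator follows counts in both
cases.

`generatePhantom()` builds the imaging arm: an elliptical brain (intensity
~30, Gaussian texture) inside a bright skull ring (150) on a 512×512×10
grid. With class-conditional probability 68/130 (LVO) or 6/170 (no LVO) a
2–6-pixel-radius dot of intensity 45–75 — safely inside the (20, 80]
window — is planted on one candidate slice inside a 30-pixel
"proximal-Sylvian" disc around one hemisphere's ROI-box centre (the
anatomical description localizes the MCA near the centre of the brain
without coordinates, so a fixed disc around each box centre is used).
Calcification-like distractor dots (intensity ≥ 120, wiped by windowing)
appear per candidate slice at rate 0.5. A geometric invariant is enforced
by construction and tested: every truth-mask voxel lands inside a cropped
ROI patch, so end-to-end segmentation training is always possible.

What the phantoms deliberately do not model: CT physics (beam hardening,
noise spectra, partial-volume effects), anatomical variability, posterior
circulation stroke, and subtle or irregular clot shapes. Passing tests on
phantoms therefore demonstrates that the machinery is correct and that the
pipeline's geometric and statistical contracts hold — not that the network
would reach clinical performance on real scans.

## Problem sizes and numerical choices

Desk-scale profiles keep every computation honest but small: the `"tiny"`
network profile (64×64 centre crop, depth 4, base 8, 128-channel
bottleneck) is used for end-to-end runs, with the `"full"` profile
(128×128, depth 5, 1024 channels) exercised for the cardinality contract.
The test suite trains the segmenter on 90 phantom patches (30 patients,
each contributing its lesion patches plus two background patches — a
positive-rich pool, which is what makes desk-scale training stable across
seeds) for 16 epochs and evaluates Dice on held-out phantoms; the level-ordering check averages
test AUC over 10 seeded 120-patient cohorts (84 train / 36 test), drawing
each patient's deep features from class-conditional pools pre-extracted
with a phantom-trained network — legitimate because a phantom depends on a
patient only through the LVO label, so pooled extraction is statistically
identical to per-patient regeneration while keeping repeated runs
affordable. The acceptance script runs one full 300-patient pipeline (200
train / 100 test) across all four families.

Numerical conventions worth knowing: Tversky smoothing ε = 1e-6; mask
binarization at 0.5; He-scaled Gaussian weight initialization; Adam
(β₁ = 0.9, β₂ = 0.999, ε = 1e-8); max-pool gradient shared among tied
maxima; all RNG derives named substreams from one master seed via a
Lehmer-style hash, so cohort, phantom and training randomness can be re-run
independently. The df = 2 chi-square tail uses the closed form
`exp(−χ²/2)`, tested against the generic survival function to 1e-12.

## Univariate statistics routing

`tableOne()` reproduces the published summary-table conventions, which were
reverse-engineered from the printed p-values: continuous variables get a
pooled-variance Student t-test; categorical variables are tabulated with
missingness as a real "Unknown" level, then routed to Fisher's exact test
when any expected cell is below 5, a Yates-corrected chi-square for 2×2
tables, and an uncorrected chi-square (df = 2 closed form) for three-level
tables. This routing reproduces the published atrial-fibrillation, smoker
and facial-weakness p-values exactly. The published limb-weakness p-value
is Fisher's exact on its 2×2 table even though no expected cell is small;
`tableOne(..., fisher_all = TRUE)` reports that column for comparison but
the automatic routing does not special-case it. Two further published
p-values (atherosclerosis, cardioembolism) match no standard test on their
printed counts and are not asserted anywhere.

## Known limitations

- The phantom is geometric, not physical; segmentation performance on it
  says nothing quantitative about real NCCT.
- The stepwise fallback under perfect separation (ridge at a fixed small
  penalty) is a pragmatic guard, not a tuned estimator.
- The SVM grid is deliberately small (6 points, 5-fold); tighter tuning is
  possible but slow inside 10-fold cutoff selection.
- Fold-wise refitting inside cutoff selection uses fold-shifted seeds, so
  cutoffs are reproducible but not invariant to changing `n_folds`.
- With 18-patient test splits, single-cell metrics are noisy by design;
  conclusions should be drawn from seed-averaged runs like the acceptance
  checks do.
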