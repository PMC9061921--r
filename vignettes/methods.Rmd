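---
title: "Methods: an MRI radiomics pipeline for rectal cancer response prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: an MRI radiomics pipeline for rectal cancer response prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Patients with locally advanced rectal cancer (LARC) receive neoadjuvant
chemoradiotherapy before surgery. Pathological response, graded on the
Mandard tumour regression scale (TRG 1--5) after resection, is only known
post-operatively; predicting it beforehand from staging MRI would let
responders (TRG 1--2) be managed less invasively. `rectomics` implements a
complete radiomics pipeline for this prediction task: quantitative texture
features are extracted from T2-weighted (T2w) volumes and apparent
diffusion coefficient (ADC) maps inside a tumour segmentation, informative
features are selected on a multicentre construction cohort, four
classifier families are tuned by cross-validation, and the chosen models
are evaluated on an external validation centre, including a *hybrid*
design in which a model trained with manually drawn masks is validated on
features computed from automatically generated masks, and vice versa.

## Image preprocessing

All processing is per modality and per mask provenance.

* **Re-segmentation.** The mask is restricted to voxels whose intensity
  lies in the closed band between the 1st and 99th percentile of the
  in-mask distribution. Percentiles are estimated with linear
  interpolation between order statistics (the common "type 7" estimator);
  ties at the bounds are retained. Applied once per modality with each
  modality's own band.
* **Discretization.** Intensities inside the re-segmented mask are mapped
  to a fixed number of grey levels (64 by default):
  `level = 1 + floor(64 * (x - min) / (max - min))`, clamped to 64 at the
  maximum; the range is the re-segmented ROI's own. A constant ROI maps to
  level 1. Fixed-bin-count discretization makes the level map invariant to
  any positive affine intensity transform, which is the property that lets
  arbitrary-unit T2w intensities be compared across scanners. No denoising
  filter and no global intensity normalisation are applied; ADC is treated
  as an intrinsically normalised quantity.
* **Slice decomposition.** The axial slices intersecting the ROI are
  processed independently (2D, "2.5D" aggregation below). Slices with
  fewer than `min_slice_pixels` ROI pixels (default 2 -- a texture matrix
  needs at least one neighbouring pair) are dropped and logged.

## The 157-feature catalogue

One shape feature (ROI volume in mm^3 from the T2w mask), four first-order
ADC statistics (mean; sample SD with the n-1 denominator; skewness
m3/m2^1.5; uncorrected kurtosis m4/m2^2, so a normal sample scores near 3),
and five texture families per modality at inter-voxel distance 1:

| family | features | neighbourhood |
|--------|----------|---------------|
| GLCM   | 25 | four in-plane directions (0, 45, 90, 135 degrees), symmetrized |
| GLRLM  | 16 | runs along the same four directions |
| GLSZM  | 16 | 8-connected constant-level zones |
| NGTDM  | 5  | 8-neighbourhood grey-tone differences |
| GLDM   | 14 | 8-neighbourhood dependence counts, tolerance 0 |

76 texture features per modality gives 1 + 4 + 2 x 76 = 157 (77 T2w, 80
ADC). `feature_catalogue()` is the single source of truth for names and
order. The GLCM set is the reference co-occurrence list of 25 (joint
maximum/average/variance, sum and difference statistics, information
measures, and so on); where reference sets differ on which co-occurrence
features to include, the shipped list is the package's documented choice
with the correct family count. For GLDM, the dependence of a pixel is the
number of its in-ROI 8-neighbours with an identical level; the matrix is
indexed by dependence + 1 so isolated pixels occupy the first column.

Conventions for degenerate inputs are fixed and tested: runs, zones and
dependences never cross the ROI boundary; out-of-ROI pixels are ignored
rather than read as level 0; GLCM correlation and the information measures
return 0 when a marginal variance or entropy vanishes; NGTDM coarseness is
capped at 1e6 when its denominator vanishes; busyness and strength return
0 when theirs do; a matrix with no mass (e.g. a slice with no neighbouring
pair along one direction) is dropped from the aggregate rather than
propagating NaN.

**2.5D aggregation.** Directional families are averaged over the four
in-plane directions within each slice, then unweighted over slices;
non-directional families average over slices only. The direction set is
closed under 90-degree rotations and reflections, so aggregated features
are invariant to those transforms -- a property the test suite verifies
numerically, alongside equivalence of every family implementation with an
independent brute-force transcription of the defining formulas on hundreds
of random slices (tolerance 1e-10 relative).

## Feature selection

Features are first min-max normalized with minima and maxima computed on
the construction rows only; validation rows transformed with those
parameters may leave [0, 1] and are deliberately not clipped (a warning
counts them). Three selection strategies are implemented:

* **Stability-resampled AUC ranking.** On each of 100 resamples (70% of
  construction patients, stratified by label so both classes are always
  present), every feature's direction-folded Mann-Whitney AUC is computed;
  features below the relevance threshold (folded AUC 0.6 by default) are
  treated as non-discriminative for that resample, and tightly correlated
  survivors (|Pearson r| >= 0.85) are pruned by discarding the lower-AUC
  member. Features surviving at least 70 of 100 resamples are kept,
  ordered by their full-construction-set AUC. Two deliberate choices
  deserve note. First, the relevance filter is what removes uncorrelated
  noise: correlation pruning alone never touches independent features, so
  without a relevance cut nearly every noise feature would survive every
  resample. 0.6 sits roughly three null standard errors above chance at
  the resample sizes involved, and setting it to 0.5 disables the filter
  (folded AUCs cannot fall below 0.5). Second, pruning decisions use the
  AUC computed once on the full construction set rather than the
  resample's: two features correlated at 0.9 with equal discrimination
  would otherwise win alternately at random, splitting their survival
  counts so that neither reaches the 70-count bar and the signal is lost.
  The prune itself is a greedy sweep in descending AUC order -- a feature
  is kept unless it correlates at or above threshold with an already-kept
  feature -- which is deterministic (name order breaks AUC ties) and
  resolves correlation chains in favour of discrimination.
* **Affinity propagation.** Features are clustered by
  responsibility/availability message passing over the similarity matrix
  of negative squared Euclidean distances between standardized feature
  columns; the exemplars are the selected subset. The shared preference is
  the median off-diagonal similarity (lifted infinitesimally so points at
  exactly the median prefer self-exemplification), damping 0.7, at most
  500 iterations, convergence declared after 30 iterations of a stable
  exemplar set. The cluster count is not set a priori. All values are
  configurable; they are conventional defaults for this algorithm.
* **mRMR (MIQ).** Greedy mutual-information-quotient ranking: the first
  pick maximizes relevance I(f; y); each later pick maximizes relevance
  divided by mean mutual information with the already-selected set.
  Mutual information is a plug-in estimate after equal-frequency binning
  into 4 bins -- a coarse but stable estimator at cohort sample sizes.

**Subset sizing.** For an ordered candidate list, models on the top-k
features are scored by mean 6-fold cross-validated accuracy on the
construction-train rows and by accuracy on the held-out construction-test
rows. The chosen size is the largest k whose test accuracy is
non-decreasing up to k while the next size shows training accuracy still
rising and test accuracy strictly falling -- the overfitting point; if the
pattern never appears, the smallest k maximizing test accuracy. The same
rule serves all three selection methods, with a linear SVM as the default
curve classifier (configurable); sizing with every downstream family would
multiply runtime without changing the character of the curves.

## Classifiers

Four families, each trained on normalized construction data over the
selected features, with responder as the positive class and every model
scoring cases by the posterior probability of response:

* **SVM** -- linear, polynomial (order 3, unit offset) and Gaussian
  kernels; box constraint tuned over {1, 2, 5, 8, 10, 15, 20, 30, 40, 50},
  a discretization of the 1--50 range that includes the values the study
  found optimal (10 polynomial, 8 Gaussian). The Gaussian kernel scale
  uses the median heuristic (gamma = 1/(2 h^2) with h the median pairwise
  training distance). Margins are calibrated to probabilities with a
  Platt-style sigmoid fitted on the training decision values; fitting the
  sigmoid in-package keeps training fully seed-reproducible.
* **Gaussian naive Bayes** -- no tuning; zero-variance features are
  floored at 1e-6 with a warning rather than yielding NaN posteriors.
* **Ensembles** -- bagging as a 100-tree random forest (sqrt(p) features
  per split), and discrete AdaBoost over 100 depth-1 stumps with unit
  learning rate.
* **Logistic regression** -- plain GLM, or forward-backward stepwise
  selection driven by deviance-based F-test p-values with entry/removal
  thresholds tuned over {0.05, 0.1} x {0.2, 0.3} (entry must be below
  removal). Perfect separation triggers a ridge refit (penalty 1e-6) with
  a warning.

Hyperparameters are chosen by stratified 6-fold cross-validated accuracy
on the construction rows, ties resolved toward the simpler candidate
(linear before polynomial before Gaussian, smaller box constraint, GLM
before stepwise). A family whose best cross-validated accuracy does not
exceed 0.5 is flagged ineligible.

## Evaluation and model selection

Sensitivity is correctly classified responders over all responders,
specificity the analogue for nonresponders; accuracy, NPV and PPV complete
the set. Percentages are rounded to the nearest integer, halves away from
zero (the rule that maps 10/16 to 63%). Proportion CIs are Clopper-Pearson;
the AUC (unfolded, responder orientation) gets a seeded stratified
bootstrap percentile CI. Construction-set performance is reported from
pooled stratified 6-fold cross-validated predictions, so construction
confusion rates are out of the full construction size and the AUC is an
honest estimate rather than resubstitution, which saturates at 1.0 for any
flexible model at these sample sizes.

The best model per mask-provenance track maximizes construction accuracy,
ties broken by PPV and then by fewer features, after excluding candidates
whose construction AUC reaches 0.99 -- the overfitting bound. When *every*
candidate reaches the bound, `select_best()` errors by default; the
pipeline instead falls back to the accuracy/PPV rule over all candidates
with a logged warning. The fallback exists because on small cohorts with
genuinely strong class structure an honest cross-validated AUC can
legitimately reach 0.99, and aborting the whole analysis in exactly the
easiest regime would make the tool unusable there; the log records that
the bound was hit so the analyst can judge.

Validation applies the frozen model and normalization to the external
split; hybrid validation is the same call with the other provenance's
feature rows. A split-tag assertion makes training refuse validation rows,
and validation refuses rows whose ids overlap the model's training ids.
Error analysis compares per-case correctness across the two tracks
(misclassified-by-manual, by-automatic, by-both) and runs two-sided
Mann-Whitney contrasts -- exact by enumeration when both groups have at
most 8 observations and no ties, otherwise the normal approximation with
tie and continuity correction -- on ROI volume and on the
manual-vs-automatic Dice coefficient. Model comparison reports McNemar's
exact test on the paired disagreements as the primary result, alongside
the unpaired two-proportion z-test that mirrors the common reporting
style; the paired test is the statistically appropriate one for two
models evaluated on the same cases.

## Synthetic cohorts

No patient data accompany the package; the generator builds desk-scale
phantom cohorts with the statistical structure the analysis assumes, and
it is first-class, tested code.

Each case is an ellipsoidal tumour (equatorial radius 5.5--8 mm by
default) in a textured volume. The T2w texture is a per-slice Gaussian
random field whose in-plane correlation length differs by response class
-- the quantity co-occurrence and run-length statistics provably respond
to -- so the class signal genuinely flows through discretization, texture
matrices and 2.5D aggregation rather than being painted into feature
space. The correlation length is specified in voxels on the native grid:
with a length in millimetres, the validation centre's coarser grid would
shift every texture feature's distribution between construction and
validation and the end-to-end checks would measure that domain shift
rather than the pipeline. The ADC map carries a class-dependent mean
(defaults 1.30 versus 1.05 in 10^-3 mm^2/s units) and is generated on a
coarser diffusion-like grid, exercising the resampling path at ingestion.

Two variability layers make the cohort honest. Voxel noise alone is not
enough: ROI-averaged features would be nearly noiseless and every
classifier would separate the classes perfectly. Each case therefore draws
its own ADC mean (between-case SD 0.10) and its own texture parameters
(log-normal jitter, SD 0.25) around the class values. The defaults put the
strongest single feature near AUC 0.95 -- strong but imperfect, the regime
in which selection and model comparison are meaningful.

Centres mirror a three-centre acquisition (voxel spacings 0.43 x 0.43 x 4,
0.47 x 0.47 x 3.5 and 0.8 x 0.8 x 3 mm); centre C cases form the external
validation set and centres A and B the construction set, split 70/30 into
construction-train and construction-test, stratified by class. TRG is
sampled within class with probabilities matching the cohort marginals
(16:26 among responders, 26:27 among nonresponders over grades 3:4). The
"automatic" mask is derived from the manual one by a seeded translation
plus boundary erosion, searched coarsely and then refined by peeling
random boundary voxels until the Dice overlap sits within +/- 0.05 of the
target (0.8 by default); targets below 0.2 are supported so the
construction-set exclusion rule can be exercised. The tabular generator
(`generate_feature_table()`) plants a known informative structure --
standardized class shift d, duplicates at correlation r, the rest noise --
and records the ground truth for recovery scoring; the single-feature AUC
it implies has the closed form Phi(d / sqrt(2)), which the tests check.

What the generator does *not* emulate: MRI physics (bias fields, motion,
partial volume), anatomically realistic tumour shapes, inter-rater
segmentation behaviour, or real scanner-specific texture; passing tests on
synthetic cohorts demonstrate that the machinery is correct and leakage-
free, not that the clinical effect sizes are attainable on real data.

## Problem sizes and numerical choices

The test suite and the acceptance script use cohorts of 20 construction
plus 10 validation cases on 26 x 26 x 18 mm fields of view, 50-resample
stability selection, and bootstrap sizes of 100--500 -- sizes chosen so a
full multi-seed end-to-end run completes in minutes on one CPU while every
stage still runs at realistic relative proportions. The end-to-end
accuracy checks use a strong-signal cohort specification (ADC means
1.40/1.00, between-case SD 0.08; texture correlation 2.4/1.1 voxels,
jitter 0.2): with 10 validation cases the accuracy granularity is 0.1, and
a moderate-signal cohort would measure sampling noise rather than pipeline
correctness. Seeds are explicit everywhere; stage seeds are derived from
the configuration seed by fixed offsets, and re-running an unchanged
configuration reproduces every number bit for bit.

## Known limitations

* 2D in-plane texture only (true 2.5D); no 26-neighbour 3D matrices, no
  wavelet or Laplacian-of-Gaussian filter banks, and no shape features
  beyond ROI volume.
* NIfTI volumes are treated as axis-aligned; the affine is read only for
  voxel spacing. Oblique acquisitions would need reorientation upstream.
* The stepwise logistic F-approximation on deviances mirrors the classic
  implementation but is approximate for binomial models.
* Printed confidence intervals depend on the CI method (Clopper-Pearson,
  bootstrap); other choices give different intervals for the same rates.
* The affinity-propagation and mRMR subset sizes reuse the
  overfitting-point rule; other sizing conventions are equally defensible.
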