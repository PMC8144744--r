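---
title: "Respiratory-phase selection and stability assessment for 4D-CT radiomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Respiratory-phase selection and stability assessment for 4D-CT radiomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phase4d)
```

## The problem

4D-CT sorts a lung cancer patient's planning scan into (typically ten)
respiratory bins, labelled 0% (peak inhale) to 90%. Radiomic features —
first-order and texture descriptors of the tumour and of a peritumoural
band — vary across these phases because of tumour motion, binning
differences, and sporadic motion artifacts. Any radiomics study must decide
which phase(s) to use. `phase4d` implements a data-driven framework for
that decision: per-patient selection of the *most stable* phase, four ways
of collapsing the phase axis into a single feature set, four
stability-assessment regimes, and a survival-modelling harness that
quantifies what each choice is worth in a clinical Cox model for distant
failure.

## The most-stable-phase rule

For each feature value $X_{F,n,Ph}$ of feature $F$, patient $n$ and phase
$Ph$, the cyclic neighbour difference is

$$\Delta X_{F,n,Ph} = |X_{F,n,Ph} - X_{F,n,Ph-1}| + |X_{F,n,Ph} - X_{F,n,Ph+1}|,$$

with wrap-around indexing (the left neighbour of 0% is 90%). The phase
minimising $\Delta X$ is the most stable for that patient–feature pair; the
patient's phase is the mode over all voting features (both ROIs, both image
types by default). Ties — in the argmin and in the mode — are broken
toward the phase cyclically closest to the 50% label, then toward the lower
phase index. This encodes the empirical prior that stable phases cluster
near exhale while keeping the rule fully deterministic. Constant features
(zero $\Delta X$ everywhere) vote via the tie-break phase by default; a
switch excludes them, since the definition gives them no real preference.

## Feature sets and stability assessment

Four single feature sets are built from the phase table: **mean** and
**median** across phases, the fixed **50% phase**, and the **personalised**
set that reads every feature from the patient's selected phase. The median
over an even phase count is the midpoint of the two central order
statistics.

Stability assessment has four regimes: *none*; *stability (10)* — drop
features whose ICC(A,1) across all ten phases has a 95% CI lower bound
below 0.85; *stability (3)* — the same over the three neighbour phases
centred on the patient's phase; and *averaging (3)* — replace each value by
the mean of the three neighbour phases. The neighbour-phase regimes only
make sense for the single-phase sets, so twelve set–assessment combinations
are valid (4 + 4 for personalised and 50%, 2 + 2 for mean and median), and
the harness rejects the rest.

ICC(A,1) is the two-way mixed-effects, absolute-agreement,
single-measurement intraclass correlation (McGraw–Wong), computed from the
two-way ANOVA mean squares, with the F-based McGraw–Wong confidence
interval (the reference whose notation the A,1 name comes from; the
implementation is checked against an explicit ANOVA oracle and an
independent reference implementation). For the personalised 3-phase
regime each patient contributes its own phase triple, with rater identity
given by relative position $-1/0/+1$ — the only pooling consistent with
patient-specific phase choices. Features with perfect observed agreement
(zero residual and zero rater variance) are given the degenerate CI
$[1, 1]$; features with zero total variance have an undefined ICC and are
conservatively classed unstable, as are features that are non-finite in any
patient–phase.

## Geometry and extraction

The peritumoural band is the set of voxels whose centre lies within 3 mm
(inside or outside) of the tumour surface, computed with a Euclidean
distance transform on the physical voxel spacing. Masks are moved between
phases by nearest-voxel translation — no interpolation, preserving voxel
count, consistent with the no-deformation assumption for a rigid tumour in
soft lung. Motion amplitude is the Euclidean norm of the per-axis ranges of
the translation set. Tumours below 64 voxels are excluded (the
conventional floor below which texture is meaningless); the bound is
inclusive at exactly 64.

High-density normal tissue (chest wall, diaphragm, bone) is removed from
the band by a documented stand-in for the original (unpublished)
correction: band voxels outside the tumour with HU above 0 are removed
together with band voxels 26-adjacent to them, and the surviving band is
eroded by one voxel against removed and exterior voxels, so only voxels
fully interior to the corrected band (or abutting the tumour core) remain.
The removal is deliberately local rather than a transitive fill: the band
is a single connected shell, so a transitive rule would discard the whole
band whenever any high-density structure touches it, instead of trimming
the attached structure as the method intends.

Extraction uses a fixed configuration: fixed bin width 25 HU anchored at
the per-ROI minimum (no re-segmentation window — air can be informative),
original and Laplacian-of-Gaussian ($\sigma = 1.5$ mm, medium edge
texture) image types, no resampling, no shape features. The 93-feature
panel per image type per ROI (18 first order, 24 GLCM, 16 GLRLM, 16 GLSZM,
5 NGTDM, 14 GLDM; 372 features per phase over two ROIs and two image
types) follows the IBSI definitions and the default enabled set of the
common extraction engines. No IBSI engine exists in this R environment, so
the feature mathematics are implemented here: GLCM and GLRLM over the 13
unique 3-D directions with feature values averaged across directions,
GLSZM zones and the GLDM/NGTDM neighbourhoods with 26-connectivity, GLDM
dependence at $\alpha = 0$ including the centre voxel. The
engine-independent invariants — the first-order mean equals the arithmetic
in-ROI mean; adding a constant to the ROI leaves all ROI-min-anchored
texture features unchanged and shifts the mean by exactly that constant —
are enforced by tests. Exact numeric parity with any particular external
engine version is not claimed.

## Selection and modelling

Unsupervised filtering runs in a fixed order giving nested subsets:
stability assessment, then removal of features with absolute Spearman
correlation to tumour volume above 0.5, then within-ROI redundancy
elimination (tumour and peritumour screened independently): while any pair
exceeds |Pearson r| = 0.5, the member of an offending pair with the
largest mean absolute correlation to all remaining features in scope is
removed and correlations recomputed (greedy re-evaluation; ties remove the
lexicographically later name). Absolute values are used throughout since
sign is irrelevant to redundancy or confounding. Features are then
z-scored (constant features dropped), before cross-validation, as the
selectors are rank- or likelihood-based.

Supervised selection runs inside 40 repeats of 5-fold event-matched
stratified cross-validation: events and non-events are shuffled separately
and dealt round-robin, so each fold's event count is within one of
proportionality ("event matching" is read as stratification on the event
indicator, the standard interpretation). Three selectors are compared:

1. univariable Cox association (Wald $p < 0.05$);
2. likelihood-ratio improvement over the fixed clinical base model
   ($p < 0.05$, one feature at a time);
3. greedy survival MRMR: relevance $= 2(\max(C, 1-C) - 0.5)$ from the
   feature's sign-aligned concordance, redundancy $=$ mean $|r|$ with
   already-selected features, adding $\arg\max$(relevance $-$ redundancy)
   while the score is positive (the difference criterion of the
   ensemble-MRMR formulation; swappable).

Per run, selected features join the clinical covariates in a Cox model
applied unchanged to the test fold. Selectors are ranked by
$C_{test} - |C_{test} - C_{train}|$ on the median concordances over the
200 runs. The signature is the occurrence-ranked feature list truncated to
the rounded (half-up) median per-run selection size, over all 200
fold-level runs; ties at the cut are broken by smaller mean within-run
selection position, then name.

The clinical base model uses tumour volume, merged lobe (middle pooled
with upper), sex, age, T stage and merged ECOG (0 pooled with 1) —
the available covariates after dropping those the source cohort could not
support for missingness. Final models are fit on the complete data; each
model's c-index is summarised over 500 bootstrap resamples in which
coefficients are refit on the resample and applied unchanged to the
original data (selection stays frozen — the models are built once on the
complete data), with a percentile 95% interval, the minimal-assumption
choice where no method is prescribed. Added value is the fraction of new
information $1 - LR_C / LR_{CR}$, the complement of the adequacy index of
the nested clinical model.

## The synthetic world

No public cohort exists, so generators provide every input with known
truth. Defaults mirror the source cohort's shape: 258 patients, 10 phases,
186 features per ROI, event fraction 44/258, clinical category frequencies
matching the published demographics (sex ≈ 52/48, median age 76, lognormal
volume with median 4.02 cm³), and designed stable phases drawn with an
exponential exhale bias placing about a third of patients at 50%.

Per patient and feature, values follow
$\text{base} + A\,(\cos\theta - 0.25\cos 2\theta) + \varepsilon$ with
$\theta$ anchored at the designed phase. A plain cosine would tie its peak
and trough for flatness; the second harmonic makes the designed phase the
unique flattest point, so the noise-free argmin of $\Delta X$ is the
designed phase for every feature by construction. The amplitude $A$ is
lognormal with median equal to the between-patient SD: phase variation
dominates the white noise (SD 0.05) for most features, the regime in which
the recovery guarantee (designed phase strictly smallest neighbour
deviation for ≥ 80% of features) holds. Artifact spikes (magnitude ten
times the noise SD, 30% of patients) are placed at phases with cyclic
distance greater than one from the designed phase: a spike adjacent to the
designed phase enters that phase's own neighbour difference and makes the
designed label false by the selection rule's own definition. Correlated
blocks share a patient-level latent factor; volume-coupled features load
on standardised log-volume; planted prognostic features are kept
independent of both so downstream filters cannot remove them as
confounded. Survival times are exponential with a Cox linear predictor on
the plants (log HR 1 per SD by default) plus a small volume effect;
censoring is independent uniform with its bound calibrated to the target
event fraction.

The 4D phantom is a soft-tissue sphere (~20 HU) in lung-density noise
(~−750 HU), translating sinusoidally (5 mm z, 1 mm x peak-to-peak by
default), with an optional +300 HU chest-wall slab and an optional
duplicated-slice artifact at one phase. Background texture is fixed in the
world frame and tumour texture moves rigidly with the sphere, so tumour
contents are phase-invariant (no deformation) while the band samples
shifting background — the geometry the method assumes.

What a green test does *not* establish: the generators produce Gaussian
textures and clean exponential survival, not CT noise physics, breathing
irregularity, or real feature distributions; recovery and calibration
results are statements about this stated world, not about any clinical
cohort. The source study's cohort-specific numbers (c-index 0.77, 58% new
information, the phase-selection histogram) are deliberately not
reproduction targets.

## Numerical choices and limitations

* Distances and kernels use physical spacing; LoG kernels are truncated at
  $4\sigma$ per axis with replicate padding, and the second-derivative
  kernel is made exactly zero-sum so constant images map to zero.
* Translation rounds to whole voxels; sub-voxel motion is therefore
  invisible, matching the mask-sampling design.
* Missing cells are never imputed: patients missing a phase are excluded
  per operation with a logged count; features non-finite anywhere are
  classed unstable.
* Cox fitting and concordance delegate to the `survival` package;
  convergence failures inside cross-validation skip the feature or run
  rather than aborting. Oracles (Newton–Raphson partial likelihood,
  exhaustive pair enumeration, two-way ANOVA) live in the test suite.
* The bootstrap redraws resamples with zero events (logged); percentile
  intervals can be narrow at small n.
* Whether the original vote pooled both ROIs and image types is not
  stated; the default votes with everything, configurable via `features` /
  `rois` arguments of `select_stable_phase()`.
* Volume correlation of a constant feature is undefined; such features are
  retained with a warning at the volume stage and removed at
  standardisation.
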