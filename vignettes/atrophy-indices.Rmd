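---
title: "Regional atrophy indices for frontotemporal dementia: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regional atrophy indices for frontotemporal dementia: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ftdindex)
```

This vignette is the package's own account of the science it
implements: the three atrophy indices, the normalization chain beneath
them, the evaluation machinery around them, the bvFTD subtype cluster
analysis, and the synthetic cohort generator that makes all of it
testable. It also records every numerical design choice that was
genuinely open, and what the synthetic experiments can and cannot show
about real data.

## The diagnostic problem

In a mixed memory-clinic population, frontotemporal dementia (FTD) is a
low-prevalence diagnosis hiding among Alzheimer's disease (AD), Lewy
body and vascular dementia, mild cognitive impairment and subjective
cognitive decline. At low prevalence, a useful imaging biomarker must
operate at high specificity — a test that is 85% specific produces more
false than true FTD alarms — so the package anchors classification at a
fixed ~95%-specificity cutoff and accepts the sensitivity that results.
Its inputs are per-subject tables of regional brain volumes in ml, as
produced by any whole-brain segmentation tool, together with a region
atlas declaring each region's hemisphere, lobe and cortical flag. All
operations are atlas-agnostic; the bundled 133-region default atlas
(102 cortical regions, 51 per hemisphere: 44 frontal, 24 temporal, 18
parietal, 16 occipital; 31 subcortical/other) mirrors the layout of
multi-atlas segmentations used in this field, with invented but
anatomically plausible names.

## Normalization

Regional volumes scale with head size and drift with age and sex, all
of which are nuisance for a disease-pattern index. The chain is applied
in a fixed order:

1. **Head size.** Proportional scaling
   `v' = v · reference_tiv / tiv`, with `reference_tiv` the mean total
   intracranial volume of the reference group. Proportional (rather
   than regression-based) scaling makes the correction exact for a
   subject whose regions all scale with TIV, and makes the downstream
   ratio indices invariant to a global rescaling of a subject's volumes
   and TIV together.
2. **Age and sex.** Per region, a linear regression of `v'` on age
   (centred at the reference mean) and a male indicator, fitted within
   the reference group only; the fitted effects are subtracted when the
   model is applied. The male indicator is uncentred; the constant
   offset this leaves is absorbed by the z-score calibration.
3. **Field strength (optional, off by default).** Additive per-level
   offsets estimated from reference residuals, relative to the most
   common level. It is off by default because scanner field strength
   had no appreciable impact on accuracy in the setting this package
   models; the option exists for cohorts where it does.

The reference group defaults to all non-FTD subjects of the training
data — consistent with the z-score reference used by the indices — and
is configurable (e.g. SCD-only for a more "normal" reference; whether a
mixed-cohort or healthy reference is preferable is genuinely open, so
the choice is exposed rather than hard-coded). Normalized volumes are
floored at ε = 0.001 ml so that log ratios remain defined; the event is
reported, since a floored volume signals either pathology far outside
the reference distribution or corrupt input. Sampling-noise guards: the
fit warns below 10 reference subjects per coefficient, and a
zero-variance covariate has its coefficient fixed at 0 with a warning
rather than failing.

## The three indices

All three are z-scores against the non-FTD calibration population:
`z = (raw − μ)/σ` with `μ`, `σ` the sample mean and n−1 SD of the raw
value over non-FTD subjects, so the reference population has mean 0 and
SD 1 by construction, and "how atrophic is this subject" is expressed
in reference-population SDs.

**API.** `raw = log(V_A / V_P)` with `V_A = Σ w_r v_r` over anterior
(frontal + temporal) cortical regions and `V_P` over posterior
(parietal + occipital) cortical regions. The weights encode where the
AD/FTD contrast is informative:
`w_r = (mean_AD v_r − mean_FTD v_r) / mean_nonFTD v_r` for anterior
regions, the reversed difference for posterior ones, negatives clamped
to zero. The clamp is part of the model — a region whose contrast goes
the "wrong" way contributes nothing rather than noise. The
parahippocampal gyrus and inferior temporal gyrus (both hemispheres)
are excluded (weight forced to 0) by default as anatomical outliers
from the otherwise compact anterior/posterior weight pattern; the list
is configurable. No other weight thresholding is applied: a
weight-magnitude threshold (e.g. 0.05) is useful for visualizing the
informative regions but is not part of the model.

**ASI.** `raw = log(V_L / V_R)` over the left and right frontotemporal
(anterior) cortical regions. How its weights should be derived is
ambiguous in principle — "defined in the same way" as API can mean the
anterior AD-vs-FTD contrast reused per hemisphere, or a left-vs-right
re-estimation. The default (`asi_weight_mode = "anterior_symmetric"`)
computes the unclamped anterior contrast per region, averages each
left/right homologous pair, then clamps; this guarantees exactly
symmetric weights, which in turn makes the raw ASI exactly antisymmetric
under a left/right mirror swap — a property worth preserving because it
makes the index interpretable as signed lateralization. The
re-estimation alternative is exposed as `"left_vs_right"`. Hemisphere
pairs are matched by stripping the `L_`/`R_` name prefix (or
`_left`/`_right` suffix), which works for any conventionally named
atlas. Because right-lateralized atrophy (rtvFTD) sits on the opposite
tail, classification offers a `two_sided` option (`|z| > 1.65`); the
default remains one-sided, matching the left-dominant PPA use case.

**TPL.** The normalized left temporal pole volume, z-scored for
consistency. It exists because single-region screening
(`screen_single_regions()`, AUC of each region's negated volume)
identifies the left temporal pole as the strongest single-region
discriminator for svPPA; screening is run on normalized volumes,
consistent with the normalize-first pipeline.

Numerical conventions: the natural logarithm is used for all ratios
(the log base only rescales μ and σ and cancels in the z-score, so any
base is equivalent; one is chosen and documented). Classification is
strictly `z < cutoff`, so a subject exactly at −1.65 is negative.
Degenerate inputs fail loudly: a non-positive weighted sum names the
side, an all-zero weight vector, a zero reference-mean volume, and a
zero-variance calibration set are all errors rather than NaNs.

## Evaluation

`roc_auc()` builds the full ROC curve over distinct score thresholds;
the trapezoidal area equals the Mann–Whitney pairwise statistic (ties
counted one half) — a property tested against a brute-force pairwise
oracle to 1e−12, and cross-checked against an independent ROC
implementation.

Two cutoff policies are provided. The parametric policy assumes
normally distributed reference scores and returns
`mean + SD · Φ⁻¹(1 − specificity)`; for a standard-normal reference at
95% this is z = −1.645, the source of the package-wide −1.65 default.
Since the calibration step standardizes the reference scores exactly,
the parametric policy is the default. The empirical policy returns the
midpoint between the k-th and (k+1)-th smallest reference scores with
`k = floor(n(1 − target))` — a cutoff placed between order statistics
rather than on one, so at most a `1 − target` fraction of the reference
falls below it. For subtype comparisons, where high specificity is not
the binding constraint, `optimal_cutoff()` scans midpoints between
adjacent distinct scores and maximizes `(sens + spec)/2`, breaking ties
toward the more specific cutoff. Likelihood ratios follow the standard
identities `LR+ = sens/(1 − spec)`, `LR− = (1 − sens)/spec`, with the
poles (specificity exactly 1 or 0) reported as undefined rather than
infinite.

`crossvalidate()` uses k = 10 folds by default, stratified by diagnosis
label — without stratification the rare groups (nfvPPA, n = 8 in the
default preset) would vanish from training folds. Everything that is
fitted — normalization, weights, μ, σ — is refitted on the training
folds only; this is enforced by construction and tested by poisoning a
test fold's volumes and asserting bitwise-unchanged training
parameters. Held-out z-scores are pooled across folds and a single ROC
is computed from the pool (pooling, rather than averaging per-fold
AUCs, matches the convention of reporting one ROC per comparison). The
cutoff is kept fixed at the calibrated −1.65 rather than re-tuned per
fold, and the specificity actually achieved on held-out data is
reported. Age stratification splits strictly below vs. at/above 70
years ("below 70" is a strict inequality; the boundary subject is in
the older stratum).

## bvFTD atrophy-subtype clustering

A sizeable minority of bvFTD patients show little cortical anterior
atrophy and are missed by API. To characterize them,
`cluster_subjects()` clusters bvFTD subjects on 18 regions of interest
spanning frontal, temporal, insular and subcortical structures (nine
homologous pairs; the set is a documented default and fully
configurable, since the original 18-ROI definition is not reproducible
from published counts alone). ROI volumes are z-standardized — against
a reference group such as SCD if supplied, else within-sample; both
modes are exposed because either standardization is defensible —
then clustered with Ward linkage (ward.D2) on Euclidean distance,
deterministic and order-invariant, and the tree is cut at k = 4
(complete and average linkage are selectable; a merge-height report
supports choosing k differently). Cluster labels are renumbered by
decreasing mean atrophy so that labels are reproducible across runs.
Cluster-vs-reference contrasts use Welch's t-test per region with
Benjamini–Hochberg correction across regions — a region-level analogue
of the original voxel-based maps, not a reproduction of them.
`crosstab_api()` then counts, per cluster, the subjects below vs.
at/above the API cutoff; on the packaged synthetic cohort the
subcortical-predominant cluster group holds the large majority of the
above-cutoff (API-negative) bvFTD cases, reproducing the qualitative
finding that motivates the analysis.

## The synthetic cohort generator

The generator emulates the structure the indices assume, not any real
dataset. Composition presets: the training preset has 1213 subjects
(317 SCD, 229 MCI, 341 AD, 40 VaD, 66 DLB, 104 other dementias, 116
FTD split 64/30/8/10/4 into bvFTD/svPPA/nfvPPA/rtvFTD/FTD+MND) and the
external-validation preset has 200 (110 AD, 20 DLB, 28 VaD, 18 SCD, 24
FTD split 10/12/2); a `small` preset (155 subjects, same shape) serves
examples and tests. Demographics follow the published baseline tables
(e.g. bvFTD age 63 ± 7, SCD 62 ± 9 years, group-specific sex ratios);
TIV is drawn per sex (female 1350 ± 110, male 1550 ± 120 ml); a global
atrophy slope of 0.25%/year centred at 65 ages the baseline volumes.

Per subject, region volumes start from fixed plausible template means
(they cancel in the ratio indices), are scaled by TIV and age, receive
the diagnosis group's fractional reductions on named region sets, and
are finally multiplied by lognormal noise (sdlog 0.05), keeping volumes
positive by construction. Group effects: bvFTD 15% anterior loss;
svPPA 30% left temporal pole compounding with 15% left temporal;
nfvPPA 15% left frontal; rtvFTD 20% right temporal; FTD+MND 10%
anterior (milder, chosen as a plausible intermediate); AD 15% parietal,
8% temporal and 20% hippocampal — parietal-dominant with milder lateral
temporal involvement, reflecting that AD's temporal signature is
predominantly medial, which also keeps the temporal AD-vs-FTD contrast
informative for the asymmetry weights; MCI a milder AD-like pattern
(5/3/8%); DLB 4% global; VaD 8% subcortical plus 4% global; other
dementias 6% global; SCD none. Half of the bvFTD subjects (the first
half of the group, deterministically) instead receive the
subcortical-predominant pattern (20% subcortical, 5% anterior) that
motivates the cluster analysis. Generation is a pure function of
(config, seed); the validation preset draws from a shifted seed stream
so the two cohorts never share noise.

What the generator does **not** emulate: segmentation failure modes,
site and scanner batch effects beyond an optional field-strength
offset, correlated regional noise (each region's noise is independent
given the subject), non-linear age effects, mixed pathology, and
diagnostic label noise. Passing tests therefore demonstrate that the
implementation is faithful to its definitions and behaves correctly
under the assumed generative structure — not that the published
clinical accuracies transfer to any particular real cohort; published
AUCs from undeposited clinical data are deliberately not used as test
targets.

## Problem sizes and test design

The test suite runs on deliberately small problems chosen to keep the
full suite under a minute while leaving each check statistically
meaningful: the 155-subject `small` preset for pipeline tests,
500–1000 subjects for normalization coefficient recovery, 100,000
reference scores for the specificity-of-the-cutoff check, 500
replicates for the FDR-control property, 20 replicates for the
chance-level AUC confidence interval, and 40 subjects (4 × 10) for
archetype cluster recovery. Stochastic assertions use fixed seeds and
tolerances derived from the sampling distribution of the checked
statistic (e.g. a three-sigma binomial bound on the family-wise error
count), not from observed runs.

## Known limitations

- The bundled atlas is synthetic: counts and structure are realistic,
  names are invented; real studies should supply their segmentation's
  atlas.
- The weight rule uses group means, so it inherits sensitivity to
  outliers in small contrast groups; the preconditions only enforce
  n ≥ 2.
- The ASI weight symmetrization is one defensible reading of an
  ambiguous definition; the alternative is provided but the two give
  different weights on asymmetric data.
- The normalization is linear in age; strongly non-linear age effects
  would leak into the indices.
- Cross-validated sensitivity at the fixed cutoff depends on the
  simulated effect sizes and is not comparable to published clinical
  sensitivities.
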