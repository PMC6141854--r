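---
title: "Methods: regional lesion loads, bootstrap significance, and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: regional lesion loads, bootstrap significance, and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lesionload)
```

## The analysis model

`lesionload` operationalizes a regional lesion-symptom analysis for ischemic
stroke. Its premise is a linear relationship between continuous regional
lesion loads and continuous 3-month clinical scores: the load of atlas
region $R$ under lesion mask $L$ is the coverage percentage

$$\mathrm{load}(R, L) = 100 \cdot
  \frac{|\{v : \mathrm{label}(v) = R \wedge L(v) = 1\}|}
       {|\{v : \mathrm{label}(v) = R\}|},$$

and each of the 121 regional loads, plus total lesion volume in ml, is
related to outcome by the Pearson product-moment correlation. Pearson's $r$
is a deliberate choice despite the mRS being ordinal: the analysis treats
both scales as continuous severity measures, and rank-based alternatives are
out of scope.

Regional loads are sparse — most regions are unlesioned in most patients —
so parametric significance tests are inappropriate. Significance is instead
the zero-exclusion rule on a **percentile bootstrap interval**: patients are
resampled jointly (load, outcome) with replacement, $r$ is recomputed per
resample (1000 by default), and the interval is formed from the empirical
$\alpha/2$ and $1-\alpha/2$ quantiles. A correlation whose interval contains
zero (endpoints included) is insignificant. No p-value backs this decision
and no multiple-comparison correction is applied; the analysis is
exploratory and its product is a ranked list of candidate regions, not
confirmatory claims about any single region.

Cohorts are dichotomized by angiographic revascularization success: TICI
2b–3 is successful, 0–2a unsuccessful. The two outcome scales are compared
by pairing each feature's NIHSS-correlation with its mRS-correlation and
applying a Wilcoxon signed-rank test over features.

## Numerical and procedural choices

**Degenerate resamples.** A bootstrap resample that draws no lesioned
patient for a feature has zero variance and no defined correlation. Such
resamples are dropped from the percentile computation and counted
(`n_boot_dropped`); if more than half of the resamples are dropped the
interval is reported *non-estimable* rather than silently extreme. Dropping
with full reporting is the least distorting treatment of a phenomenon that
any sparse-load cohort exhibits.

**Quantiles.** Percentile intervals use linearly interpolated empirical
quantiles (R's default type 7). The basic and BCa variants were not used:
the plain percentile method is the minimal reading of "a 95% confidence
interval from the resampled correlations", and the package's coverage is
validated directly by simulation (bivariate normal, true $r = 0.5$,
$n = 55$: empirical coverage of the nominal 95% interval falls in the low
90s, the familiar mild undercoverage of the percentile method at this $n$ —
`scripts/acceptance.R` recomputes this number).

**Thresholds.** Delineation thresholds are strict inequalities exactly as
conventionally printed: a voxel is ischemic core iff ADC $< 600 \times
10^{-6}\,\mathrm{mm^2/s}$ and perfusion deficit iff Tmax $> 6$ s. Boundary
voxels are excluded. Prediction maps binarize at $\ge 0.5$ (inclusive, the
argmax-of-two-classes convention); how a continuous prediction map should
become a binary lesion is genuinely open, so the threshold is a parameter.
No morphological post-processing is applied by default; an optional
minimum-cluster-size filter (6-connectivity) exists but is off, because the
delineation model is pure thresholding.

**Atlas representation.** The atlas is a maximum-probability (hard-label)
volume: one label per voxel. The load formula presupposes a crisp region
definition; probabilistic (4D) atlas weighting is a non-goal. Lesion voxels
on unlabeled background count toward total volume but no regional load, and
are reported per patient (`unlabeled_voxels`) so that signal lost outside
the parcellation is visible rather than silent. Region denominators are
computed once from the atlas, with no per-patient masking. Loads are
computed on the common normalized grid; whether total volume should be
measured in native space instead is unknowable here, and the normalized
measure is used consistently.

**Wilcoxon signed-rank.** Pairs are all features with a defined correlation
in both profiles; zero differences are dropped; absolute differences are
ranked with average ranks under ties. For $\le 25$ retained pairs the
two-sided p-value is exact: the null distribution of the positive-rank sum
is enumerated over all $2^n$ sign assignments (dynamic programming over
doubled ranks keeps average ranks integral), and the p-value is the null
probability of a rank sum at least as far from its mean as observed. Beyond
25 pairs a normal approximation with tie correction and continuity
correction is used. `stats::wilcox.test` is not the implementation — its
exact path refuses ties — but serves as an independent cross-check on
tie-free cases in the test suite.

**Reproducibility.** Every bootstrap requires an explicit seed.
`correlate_features()` derives one RNG stream per feature from the master
seed and a mixed (Lehmer-scrambled) hash of the feature id, so adding,
removing, or reordering features never perturbs any other feature's
interval, and near-identical ids land on unrelated streams. All RNG use is
wrapped so the caller's `.Random.seed` is untouched.

## What the synthetic cohort emulates

The generator produces a cohort with the statistical structure the analysis
assumes, plus full ground truth. Its defaults are the study conditions the
package is validated under; each has a unit and a rationale:

| parameter | default | meaning |
|---|---|---|
| `grid` | 64³ voxels at 2 mm | common analysis grid (48³ in the package's multi-cohort validation suites, for runtime) |
| `n_wm_regions`, `n_gm_regions` | 29, 92 | parcellation sizes of the targeted 121-region atlas |
| `n_patients` | 55 | cohort size; with the default TICI mix ≈ 35 successful / 20 unsuccessful |
| `tici_distribution` | 0.07/0.08/0.19/0.26/0.40 | probabilities over grades 0, 1, 2a, 2b, 3 |
| `eloquent_regions` | `"auto"` (3 regions, 20 points each) | outcome-driving regions; see below |
| `volume_weight` | 0.05 NIHSS/ml | total-volume contribution to severity |
| `noise_sd` | 3 NIHSS points | outcome noise |
| `mrs_noise_sd` | 5 NIHSS points | rater/physiology blur before mRS banding |
| `penumbra_salvage_by_tici` | 0.05 → 0.95 | fraction of the penumbra shell salvaged, non-decreasing in TICI |
| `lesion_volume_meanlog`, `sdlog` | log(25), 0.8 | log-normal target penumbra volume (ml); the median is ≈ 5–7% of the synthetic brain, matching realistic final-infarct fractions |
| `core_fraction` | 0.25–0.5 | core volume as a fraction of the penumbra |

**Anatomy.** The brain is an ellipsoid partitioned into an inner
white-matter compartment and a gray-matter shell, each split into regions by
nearest-seed assignment with seeds mirrored across the midsagittal plane, so
regions come in left/right homologue pairs.

**Lesions.** The emulated cohort consists of proximal
middle-cerebral-artery occlusions, so lesion seed voxels are drawn with
Gaussian jitter around a fixed mid-lateral territory epicenter of a
uniformly chosen hemisphere — not uniformly over the brain. The penumbra is
the target number of nearest brain voxels in that hemisphere; the core is
its inner fraction (by distance from the seed); the final lesion removes the
salvaged outer shell fraction, so core ⊆ final ⊆ penumbra holds by
construction and unsuccessful revascularization yields larger final lesions.

**Parameter maps.** ADC is 750e-6 mm²/s in healthy brain and 450e-6 in the
core with ±75e-6 noise; Tmax is 2 s outside and 9 s inside the penumbra with
±1.5 s noise. The noise amplitudes leave a margin on both sides of the
600e-6 and 6 s thresholds, so thresholding recovers the ground-truth masks
*exactly* — delineation recovery is an exact test, not a statistical one.
The prediction map is confidently above 0.5 inside the final lesion and
decays below 0.5 outside, so binarization recovers it too.

**Outcome.** NIHSS is linear in the designated eloquent-region loads and
total volume plus Gaussian noise, clipped to 0–42 and rounded. With
`eloquent_regions = "auto"` the three designated regions are the 3rd–5th
regions by distance from the left territory epicenter, 20 NIHSS points per
fully-lesioned region. Two geometric considerations drive this choice.
First, all designated regions sit in one hemisphere: marginal correlations
are the analysis's instrument, and splitting effect weights across
hemispheres makes each side's lesions suppress the other side's marginal
load-outcome relationship. Second, the innermost territory regions are
skipped because they are almost always fully covered whenever the territory
is lesioned — near-binary loads that push the linear predictor into the
42-point ceiling — whereas slightly off-center regions receive graded
partial loads and keep the outcome model in its informative range.

**mRS.** The mRS views the same impairment through additional blur (5 NIHSS
points) and the conventional clinical severity banding (NIHSS 0–1 → mRS 0,
2–4 → 1, 5–8 → 2, 9–13 → 3, 14–20 → 4, 21+ → 5; grade 6, death, is not
generated). Deterministic coarseness, not merely additive noise, is what
makes mRS the weaker correlate: a purely additive noise model turns out to
shift all features' correlations together (one shared noise vector across
the cohort), which makes the NIHSS-vs-mRS contrast a coin flip at realistic
cohort sizes rather than a stable property. The band transform attenuates
every feature's correlation deterministically, so NIHSS-superiority is
reproducible across simulated cohorts, as the paired-profile Wilcoxon test
in the validation suite checks across 50 seeds.

**What it does not emulate.** No biophysical diffusion/perfusion modeling,
no vascular-territory geometry beyond the epicenter convention, no imaging
artifacts, no registration error (all volumes are generated on the common
grid), and no cohort demographics. Passing validation on this generator
shows the pipeline's statistical machinery behaves as specified under its
own assumptions; it does not show that real lesions satisfy those
assumptions.

## Validation scale

The routine test suite and the multi-cohort validation checks run at sizes
chosen as the package's standard validation configuration: 48³ voxel grids
at 2 mm, cohorts of 55 patients, 50 independent master seeds for the
parameter-recovery and scale-comparison suites, 500 replicates × 1000
resamples for bootstrap coverage, and exhaustive enumeration oracles at
small n (27 resamples at n = 3; all sign assignments up to 12 pairs). The
bootstrap size does not enter the ranking or Wilcoxon checks (both are
functions of the point correlations only), so those suites use a token
bootstrap.

## Known limitations

- Pearson correlation on an ordinal mRS and a bounded NIHSS; ceiling/floor
  effects attenuate correlations near the scale limits.
- Marginal, single-region correlations: collinear neighboring regions load
  together, and a region can rank highly purely by proximity to a truly
  eloquent one. Network-level effects are out of scope.
- The percentile interval mildly undercovers at n ≈ 55; the package reports
  the phenomenon rather than correcting it (BCa is out of scope).
- Non-estimable features (sparse loads) are reported, not imputed; cohorts
  with very small splits will produce many of them.
- The atlas must fully define the feature space; lesion signal outside the
  parcellation appears only in total volume and `unlabeled_voxels`.
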