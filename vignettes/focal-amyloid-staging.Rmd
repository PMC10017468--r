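---
title: "Methods: focal amyloid staging from two-ligand PET SUVR profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: focal amyloid staging from two-ligand PET SUVR profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(focalstage)
library(dplyr)
```

## The problem

Global amyloid positivity on PET is usually decided by thresholding a single
cortical-average SUVR (or its Centiloid transform). That throws away spatial
information: a participant can carry clearly elevated tracer uptake in one or
a few regions while the cortical average stays below the global cutoff.
`focalstage` implements a quantitative pipeline for exactly this situation:

1. aggregate parcel-level uptake into ten composite regions (frontal, lateral
   temporal, parietal, cingulate, striatum; left/right) and a global cortical
   target, all referenced to the whole cerebellum (`aggregate_profiles()`);
2. convert global SUVR to direct-comparison Centiloid (dcCL) units so the two
   ^18^F ligands, florbetaben (FBB) and flutemetamol (FMM), share one burden
   scale (`suvr_to_cl()`);
3. derive ligand- and region-specific SUVR positivity cutoffs from a
   cognitively unimpaired (CU) reference sample by iterative Tukey-fence
   outlier removal (`derive_regional_cutoffs()`);
4. classify every participant as G−F− (global- and focal-negative), G−F+
   (global-negative but focally involved), or G+ (globally positive), with a
   focal (1–9 regions) versus whole-brain (10 regions) subtype
   (`stage_cohort()`);
5. compare groups on cognitive and morphometric outcomes (ANCOVA with Tukey
   post hoc, Mann–Whitney, Jonckheere–Terpstra trend), compare lobar
   involvement frequencies by bootstrap, and contrast the G/F grouping with a
   pure Centiloid-band grouping by AIC (`compare_groups()` and friends).

Because clinical scans cannot ship with a package, a synthetic cohort
generator (`generate_cohort()`) reproduces the statistical structure the
analysis assumes, so every stage is exercised end to end by code alone.

## Regional aggregation

A region's SUVR is the volume-weighted mean uptake of its VOIs divided by
the whole-cerebellum uptake. Volume weighting corresponds to pooling voxels
across parcels and degenerates to the unweighted mean for equal volumes.

The default map (`default_region_map()`) has 28 VOI entries — 14 per
hemisphere. Parietal (superior/inferior parietal, supramarginal, angular,
precuneus), lateral temporal (superior/middle/inferior temporal), cingulate
(anterior/posterior), and striatal (caudate, putamen) entries follow AAL
parcel naming directly. The nine frontal AAL parcels per hemisphere
(superior and middle frontal, medial superior frontal, opercular and
triangular inferior frontal, supplementary motor area, and the three orbital
parcels) are pooled into two composite VOIs (dorsomedial and orbital); the
published region listings name these structures without fixing parcel
indices, so the map documents its own choice and is fully editable — any
table with `voi_name`/`lobe`/`hemisphere` columns that reaches all ten
regions is accepted (`read_region_map()`).

The global cortical target defaults to the union of all frontal, lateral
temporal, parietal, and cingulate VOIs (striatum excluded). This is an
approximation: dcCL pipelines define the cortical target VOI from group
difference images, which cannot be rebuilt from tabular parcel means. The
VOI list is a plain argument (`global_vois`) for users who have their own
target definition.

`extract_voi_means()` covers the upstream step for users starting from a
registered PET volume plus an integer label volume (arrays or NIfTI files):
per label, the mean intensity and the voxel count. Spatial normalisation,
registration, and partial-volume correction are out of scope — inputs are
assumed already in a common space, and no partial-volume correction is
applied anywhere in the pipeline.

## Centiloid conversion and global positivity

The dcCL conversion is affine,

$$\mathrm{CL} = 100 \times \frac{\mathrm{SUVR}_{ind} -
\mathrm{SUVR}_{YC\text{-}0}}{\mathrm{SUVR}_{ADCI\text{-}100} -
\mathrm{SUVR}_{YC\text{-}0}},$$

anchored at the mean SUVR of an amyloid-negative young-control group (0 CL)
and of a typical amyloid-positive cognitively impaired (ADCI) group
(100 CL). Anchor means are ligand-specific configuration
(`ligand_calibration()`); the generator ships self-consistent anchors
(`generate_anchor_sets()`).

Global positivity is `CL >= cutoff`, default 25.11 CL, overridable (20 and
40 CL are the usual sensitivity settings). The boundary convention is not
fixed by the source methodology; counting the boundary as positive is this
package's documented choice. `derive_cl_cutoff_roc()` re-derives a cutoff
from data by maximising Youden's J over all candidate midpoints against a
binary standard of truth; which ROC criterion the original calibration used
is not stated, so Youden — the standard choice for biomarker thresholds — is
the implemented default, with ties broken toward the lower threshold.

## Regional cutoffs by iterative outlier removal

For each region and ligand separately, using only CU participants scanned
with that ligand:

1. compute Q1, Q3, and IQR of the retained SUVR values;
2. remove every value outside the Tukey inner fences
   $[Q1 - 1.5\,\mathrm{IQR},\; Q3 + 1.5\,\mathrm{IQR}]$ (both tails in the
   same pass; removed values never re-enter);
3. repeat until a pass removes nothing;
4. cutoff = maximum of the final retained sample, increased by 2.5% of
   itself (`max * 1.025` — a relative increment, not an absolute one).

Numerical choices, all parameterised:

* **Quartile convention.** Linear interpolation of order statistics
  (`stats::quantile` type 7), the common default; Tukey-hinge-like
  quartiles are available via `quartile_type = 2`. The source methodology is
  silent on the convention.
* **Minimum sample size 8.** Below that, quartiles of tiny sets make the
  fences meaningless, so the derivation refuses to run.
* **Termination.** Each non-terminal pass removes at least one value, so the
  loop ends within `n` passes; the full per-pass trace (counts, quartiles,
  fences) is returned for audit and serialises to JSON
  (`write_regional_cutoffs()`).

Known limitation, inherited from the method: regions with a wide SUVR
dynamic range in the reference sample (notably the cingulate) push their own
fence upward, biasing the cutoff high. No correction is applied.

## Staging

Regional positivity is strict (`SUVR > cutoff`); global positivity is
`CL >= cutoff`. Both boundary conventions are exposed as arguments because
neither is externally fixed. Group assignment: G+ for every
globally positive participant; otherwise G−F+ with ≥ 1 involved region,
else G−F−. The subtype distinguishes none / focal (1–9) / whole-brain (10).
Global positives are expected to be whole-brain type; a globally positive
participant with zero involved regions is flagged `discordant` rather than
silently relabelled, preserving the distinction between "globally positive"
and "whole-brain involved" that the three-group label collapses.

## Statistics

* **ANCOVA** (`compare_groups(..., "ancova_age")`): linear model
  `outcome ~ age + group`; the group F test is the sequential test with the
  group term last, i.e. adjusted for age. Covariates are configurable; only
  age is adjusted by default, matching the analysis this package
  accompanies.
* **Tukey post hoc**: `stats::TukeyHSD` without covariates; with covariates,
  pairwise contrasts of covariate-adjusted means (emmeans) with
  studentized-range adjustment.
* **Mann–Whitney**: `stats::wilcox.test` — exact for small untied samples,
  normal approximation with tie correction otherwise.
* **Jonckheere–Terpstra** (`jonckheere_trend()`): hand-implemented (no
  suitable dependency): JT = sum of pairwise Mann–Whitney counts over
  ordered group pairs, ties counting 1/2; p from the normal approximation
  with the standard tie-corrected null variance, with an optional seeded
  permutation p. Fully tied data have zero null variance and return p = 1.
  The hypothesised order is the group factor's level order
  (G−F− → G−F+ → G+).
* **Involvement-frequency bootstrap**
  (`involvement_frequency_bootstrap()`): restricted to focal-type
  participants (1–9 involved regions; whole-brain participants are excluded
  because every lobe is involved by definition, which would wash out any
  ordering — `include = "any_involved"` lifts this). A lobe counts as
  involved if either hemisphere is. Participants are resampled with
  replacement; the two-sided p for a lobe pair is
  `2 * min(P(f_A <= f_B), P(f_A >= f_B))` over resamples, floored at
  `1/n_resamples` on the −log10 scale. The p construction is this package's
  choice; only the −log10 display scale is externally given.
* **AIC grouping comparison** (`compare_groupings_aic()`): the same Gaussian
  linear model fitted under the G/F grouping and under a Centiloid-band
  grouping (negative < 10 ≤ subthreshold < 25.11 ≤ positive); lower AIC
  wins, ties to the G/F grouping.
* No multiple-testing correction is applied beyond Tukey's adjustment,
  matching the reporting style of the accompanying analysis.

## The synthetic cohort generator

`generate_cohort()` draws, per participant: a diagnosis (CU/aMCI/dementia at
23.6/41.3/35.1%), a ligand (51.4% FBB), a latent stratum, a latent burden
scalar, lobe and region involvement, SUVR values, and outcomes.

**One-factor burden model.** A single latent burden scalar with
lobe-specific onsets replaces independent regional processes. This is the
simplest model that reproduces the monotone relation between global
Centiloid and involved-region count and the spread ordering parietal →
frontal/temporal → cingulate → striatum (striatum last). True inter-regional
correlation structure in patients is not publicly characterised; this is a
modelling choice, and passing tests show internal consistency of the
pipeline, not fidelity to any real cohort's covariance.

**Strata.** Global positivity probability per diagnosis is 20.6/56.8/84.7%;
among global-negatives, 9/18/27% are focal-positive, giving ≈ 6.4% G−F+ and
≈ 58% G+ overall. Burden supports are disjoint with gaps (negatives
< 0.15, focal 0.25–0.40, positives ≥ 0.70 with a Gamma right tail), so the
planted labels are recoverable and the impaired strata carry heavy right
tails. The positive stratum's floor (0.70) lies above the striatal onset
(0.58), making global positives essentially whole-brain type — consistent
with equating "globally positive" and "whole-brain" at the group level — and
leaving the focal-type bootstrap set dominated by G−F+ participants, whose
lobe involvement is drawn to match the target frequencies
(38.8/32.5/32.4/26.1/13.0% for parietal/frontal/temporal/cingulate/striatum,
adjusted for conditioning on ≥ 1 involvement by a fixed-point iteration).

**Scales.** FBB baseline SUVR 1.10 vs FMM 1.00 with a 0.9 relative FMM gain,
so FBB sits on the higher SUVR scale and all FBB cutoffs exceed FMM cutoffs.
Involved regions gain `0.12 + 0.45 * burden` SUVR (ligand-scaled);
uninvolved regions get a small diffuse term. Noise decomposes into a
subject offset (SD 0.04), lobe noise shared between hemispheres (SD 0.03),
and hemisphere noise (SD 0.015) — hemispheres of a lobe are symmetric up to
small independent noise, and an involved lobe becomes bilateral with a
probability that grows with burden. The global SUVR is the lobe-weighted
mean of the cortical regions (frontal 0.40, temporal 0.22, parietal 0.30,
cingulate 0.08 — approximate lobar volume shares).

**Anchors.** The ADCI anchor group is drawn at burden 1.9 ± 0.15 with full
involvement, placing the global cutoff of 25.11 CL at burden ≈ 0.48 —
inside the gap between the focal and positive strata, which is what makes
staged labels agree with planted labels at ≥ 95%.

**Outcomes.** MMSE (0–30), SVLT delayed recall (0–12), hippocampal volume,
and AD-signature cortical thickness get group means ordered
G−F− > G−F+ > G+ with Gaussian noise, truncated to their score ranges, plus
a linear age slope; age itself differs by group (the G−F+ stratum is
oldest), so age is a genuine confounder and covariate adjustment is
exercised, not decorative. APOE4, sex, and visual-read positivity are
Bernoulli by group.

**What the generator does not emulate:** scanner and reconstruction effects,
partial-volume effects, longitudinal change, continuous (non-mixture) burden
distributions, and realistic inter-regional covariance beyond the one-factor
model. Results on synthetic data therefore validate the pipeline's
correctness and power under its stated assumptions — not clinical
performance.

## Problem sizes and determinism

The package's own validation runs use: the default cohort of n = 900
(group recovery, threshold sweeps, trend tests), 1,000 null replicates of
n = 200 for the ANCOVA type-I-error check, and a cohort of n = 20,000
(≈ 1,350 focal-type participants) for lobar-frequency-ordering recovery —
at n = 900 only ~60 focal-type participants remain and an ordering of
frequencies 0.388 vs 0.325 is underpowered by design, so the ordering is
checked where the generator's asymptotics are visible. All stochastic steps
take explicit seeds, restore the caller's RNG state, and are bit-reproducible
given seed + configuration.

## A worked run

```{r pipeline}
cfg <- cohort_config()
sim <- generate_cohort(cfg, seed = 42)
calibs <- calibrations_from_anchors(generate_anchor_sets(cfg, seed = 42))

cu_ids <- sim$cohort$participant_id[sim$cohort$diagnosis == "CU"]
cutoffs <- lapply(setNames(c("FBB", "FMM"), c("FBB", "FMM")), function(lg) {
  derive_regional_cutoffs(
    filter(sim$profiles, ligand == lg, participant_id %in% cu_ids), lg)
})
tidy(cutoffs$FBB)

staged <- stage_cohort(sim$profiles, cutoffs, calibs)
group_counts(staged)

d <- left_join(sim$cohort, staged, by = c("participant_id", "ligand"))
glance(compare_groups(d, "svlt", "ancova_age"))
glance(jonckheere_trend(d, outcome = "mmse", group = "group",
                        alternative = "decreasing"))
tidy(compare_groupings_aic(d, "hv"))

fb <- involvement_frequency_bootstrap(staged, n_resamples = 1000, seed = 42)
fb
```

```{r plots, fig.width = 6, fig.height = 4}
autoplot(staged)
autoplot(fb)
```
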