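---
title: "Predicting parotid mean dose from overlap volumes: model and methods"
author: "ParotidOverlap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting parotid mean dose from overlap volumes: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ParotidOverlap)
```

## The problem and the model

Sparing the parotid glands is one of the central trade-offs of head-and-neck
radiotherapy planning: mean parotid doses above about 26 Gy risk permanent
loss of salivary function (xerostomia), while the elective and boost target
volumes often wrap around or even invade the glands. For helical
(Tomotherapy-style) delivery, whose dose gradients are steep, the achievable
mean parotid dose turns out to be predictable from contour geometry alone —
before any planning is done.

The predictor family is the *fractional overlap*

$$\mathrm{OLV}(P, T) = \frac{|P \cap T|}{|P|}$$

of the parotid \(P\) with a target \(T\): the combined PTV (union of all
dose levels) and its 5 / 10 mm isotropic expansions (`OLV_CT`, `OLV_CT05`,
`OLV_CT10`), and the highest-dose PTV and its 5 mm expansion (`OLV_HD`,
`OLV_HD05`). A parotid is *positive* when its mean dose \(D_{mean}\)
strictly exceeds the 26 Gy tolerance; 26 Gy exactly is negative.

Parotids are stratified by the highest dose level they touch:

* **Scenario A** — the parotid overlaps the high-dose PTV. By default the
  gate uses the 5 mm *expanded* high-dose PTV (`groupingMode = "expansion"`),
  because that is the statistic the decision threshold is defined on; the
  alternative `"ptv"` mode gates on the raw PTV, which is the stratification
  used when plotting dose against per-level overlap.
* **Scenario B** — no high-dose overlap, but the parotid overlaps an
  intermediate-dose PTV.
* **Scenario C** — low-dose overlap only. **none** — no overlap at all.

The shipped decision rule (`PredictionRuleConfig()`):

| scenario | prediction                                    |
|----------|-----------------------------------------------|
| A        | exceeds tolerance iff `OLV_HD05` > 0.083      |
| B        | exceeds tolerance iff `OLV_IM` ≥ 0.25         |
| C / none | spared                                        |

The scenario-A threshold 0.083 is the clinically calibrated operating point
(reported with sensitivity 0.81 and specificity 0.90 on its source cohort).
`calibrateRule()` re-derives it from any cohort via the ROC of `OLV_HD05`
restricted to scenario-A records; the recalibrated value is returned in a
new config and never silently replaces the shipped default.

Two boundary conventions are fixed deliberately. The ROC (and hence the
rule) calls a record positive when the score is *strictly greater* than the
threshold, so `OLV_HD05 = 0.083` exactly predicts sparing. The scenario-B
comparison is *inclusive* (≥ 0.25): sparing is described as likely below
25%, and the observed exceedances sat just above (0.26, 0.34), so the
boundary itself is called positive but flagged `indeterminate` in the
report text — conservative for a toxicity screen.

## Geometry: millimetre-true expansion

Isotropic expansion is implemented as a Euclidean distance transform (a
separable lower-envelope algorithm in compiled code) with per-axis spacing:
an output voxel is occupied iff the distance from its center to the nearest
occupied input voxel *center* is ≤ the margin in millimetres. This is
mm-true under anisotropic voxels, unlike structuring-element dilation in
voxel units, whose physical reach would change with grid resolution.
Distances are center-to-center; the inside test for rasterization is the
even–odd rule at voxel centers (multiple polygons on a slice XOR together,
honoring holes), matching common treatment-planning-system behavior, and
contour z positions snap to the nearest slice within half a slice spacing.
Expansions are not clipped to a body contour, and grids are assumed padded
so structures of interest do not touch the array boundary (expansions clip
there). Overlap statistics are computed on the structure grid, independent
of the dose grid — they are purely geometric. Whether the combined PTV is
expanded before or after the union is immaterial here: for distance-
threshold dilation the expansion of a union equals the union of expansions.

## Dosimetry conventions

`meanDose()` averages the dose sampled at every occupied structure-voxel
center, using trilinear interpolation when structure and dose grids differ
(on identical grids this reduces exactly to voxel lookup — there is a test
for that). `coverageFraction()` counts voxels at or *above* the threshold
(inclusive), so V100% of a uniformly-at-prescription target is 1. The plan
filter keeps plans with highest-PTV V100% ≥ 0.90 — inclusive at the
boundary, since exclusion is defined by coverage strictly below 90% — and
its exclusion log records that the companion clause about compromised
coverage overlapping the GTV is *not evaluated*: GTV geometry is outside
this data model.

## Regression, selection, ROC

`fitLinear()` is ordinary least squares with an intercept; its AIC uses the
full Gaussian log-likelihood with the error variance counted as a parameter,

$$\mathrm{AIC} = n\log(2\pi) + n\log(\mathrm{RSS}/n) + n + 2(p + 2),$$

so values match `stats::AIC()` on `lm` fits and are comparable with
mainstream software. Only AIC *differences* drive selection, but fixing the
constant makes the slot testable. `backwardStepwiseAIC()` starts from the
full model, removes the single variable whose removal lowers AIC most, and
stops when no removal lowers AIC; ties are broken by removing the
lexicographically last name, so the procedure is deterministic. The
intercept is never removed.

`rocCurve()` sweeps −∞, the midpoints between consecutive distinct scores,
and +∞, and integrates sensitivity over 1 − specificity by trapezoid, which
equals the Mann–Whitney pair statistic with ties counted ½ (property-tested
against a pair-counting oracle). "Best overall sensitivity and specificity"
is operationalized as the Youden index \(J = \mathrm{sens} + \mathrm{spec}
- 1\); ties resolve to the smallest threshold (the highest-sensitivity
choice, conservative for screening), and `criterion = "closest01"` offers
the closest-to-(0,1) alternative. Both parotids of a patient enter the
cohort as independent records; no clustering correction is applied, which
mirrors how such cohorts are conventionally analyzed.

Dose levels are ranked *per plan* (highest = high, lowest = low, middle =
intermediate) rather than by absolute Gy bands, because common prescription
schemes place 60 Gy sometimes as an intermediate and sometimes as the
lowest level; relative ranking resolves every scheme unambiguously. A
two-level plan has no intermediate level; its `OLV_IM` is `NA` and counts
as no overlap in scenario gating.

## The synthetic cohort: a stated world

No clinical data ship with the package, so `generateCohort()` builds plan
bundles with the statistical structure the analysis assumes — it is the
test bed for everything downstream, not an attempt at anatomical realism.

Per patient (defaults in `syntheticCohortParams()`):

* **Grid**: 96 × 72 × 56 voxels at 2 mm isotropic spacing, centered.
* **Prescriptions**: one of ten clinically observed schemes (2–4
  simultaneous levels, 54–70 Gy), sampled with the schemes' observed case
  weights.
* **Targets**: an ellipsoidal high-dose PTV near the midline (base
  semi-axes 22/26/25 mm, ±15% jitter); lower levels are distance-threshold
  expansions of it, one sampled step of 6–8 mm to the first lower level and
  2.7–3.7 mm per further level.
* **Parotids**: two lateral ellipsoids with analytic volumes drawn inside
  11.35–55.18 cc (sampled strictly interior to the range so voxelized
  volumes stay within it at 2 mm spacing), axis ratios 1.2–1.6 (AP) and
  1.6–2.2 (SI).
* **Dose**: \(D(x) = \max_l Rx_l \exp(-\max(0, d_H(x) - m_l)/\lambda)\)
  with \(d_H\) the distance to the high-dose PTV and \(m_l\) the level's
  cumulative margin — every PTV receives at least its prescription, the
  high-dose PTV exactly its prescription, and dose decays exponentially
  with length \(\lambda = 5\) mm beyond each target. The 5 mm falloff
  embodies the delivery's ~0.5 cm effective field size — and makes the
  hypothesis that the 5 mm-expanded overlap predicts best *testable*, since
  \(\lambda\) is a parameter. Expressing each lower level's distance as
  \(\max(0, d_H - m_l)\) (exact up to voxelization for these nested,
  distance-thresholded targets) keeps generation to two distance
  transforms per patient.
* **Placement**: each parotid draws a scenario target (35% A, 20% B, 25% C,
  20% none) and a target overlap (scenario A: uniform on 0.005–0.40), then
  a lateral-offset bisection achieves that overlap on the actual grid.
* **Noise**: one Gaussian perturbation (sd 1.5 Gy) added to each parotid's
  dose voxels — cohort-level scatter of the mean dose, not per-voxel noise,
  which is what the downstream regressions actually see.
* **Coverage**: recorded V100% is computed from the emitted dose grid,
  except that with probability 0.05 a plan simulates a coverage failure
  (uniform on 0.80–0.895) at the *metadata* level, to exercise the plan
  filter; the dose grid itself always covers the PTV, as no beam model
  exists here.

Every overlap value in the emitted tables is the package's own geometry
recomputed on the emitted masks, so generator and analysis path cannot
drift apart (tested to exact equality).

**Calibration of the stated world.** The expansion steps between dose
levels are the one free quantity the cohort description does not fix, and
they control where the noise-free mean dose crosses 26 Gy as a function of
`OLV_HD05`. They were calibrated once — by sweeping a canonical mid-size
parotid against the canonical 70/59.4/56 Gy plan and then checking the
recovered cohort-level threshold — so that the crossing sits at the
clinical threshold 0.083, and then frozen at 6–8 mm / 2.7–3.7 mm. Nothing
was adjusted afterwards. Two honest consequences of this world are worth
recording: four-level schemes (7% of plans) cross at smaller overlaps than
three-level ones, adding realistic scatter; and the *infinite-n* noise-free
Youden boundary sits slightly above the design point (≈ 0.100, measured
once at 600 patients and frozen as the reference for the convergence test)
because the optimal threshold falls in the score gap between sparse
negatives and positives rather than exactly at the dose crossing. With the
default 1.5 Gy noise and study-sized cohorts, recovered thresholds land
within a few thousandths of 0.083.

What a green test on this world does **not** establish: fidelity to any
clinical dose engine (no beam model, no optimizer, no scatter), realistic
anatomy (ellipsoids only), inter-observer contouring variation, or the
clinical cohort's overlap distribution, which the source study reports only
through scattered maxima. The generator establishes *internal* correctness:
that geometry, dosimetry, regression, ROC calibration and the decision rule
compose the way the model claims.

## Numerical choices and degenerate inputs

* Expansion thresholds are inclusive (≤ margin); margin 0 is the identity.
* `fractionalOverlap` on an empty parotid is an error (undefined ratio),
  not 0.
* An all-constant outcome gives \(R^2 = 0\) by convention (zero total sum
  of squares); a perfect fit gives AIC −∞, which orders correctly in
  selection.
* Rank-deficient design matrices error naming the dependent columns.
* ROC requires both outcome classes and errors with diagnostic counts
  otherwise (`calibrateRule` reports how many scenario-A records fell on
  each side of tolerance).
* Plan bundles store masks and dose as ascii NRRD (text-only, exact
  round-trip is tested bit-for-bit) plus a JSON sidecar; a reader for
  clinical DICOM RT files is deliberately out of scope so the package
  builds and tests with no clinical data.

## Known limitations

The rule is a screen, not a planning system: it predicts the binary
tolerance question only, not dose in Gy. It deliberately does not
distinguish ipsilateral from contralateral glands — the model is purely
volumetric. Scenario B rests on very few positive observations (hence the
indeterminate flag at its boundary), and the synthetic world, built from
concentric target expansions, cannot produce large intermediate-dose
overlaps without high-dose proximity, so the scenario-B branch is validated
on constructed fixtures rather than generated cohorts. Finally, the
stepwise-AIC selector retains a pure-noise predictor with probability
≈ 0.16 each (a property of the AIC penalty itself, reproduced exactly by
MASS's implementation), so "selects exactly the driving variable" holds in
roughly 70% of simulated cohorts, not nearly always.
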