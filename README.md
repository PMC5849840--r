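# ParotidOverlap

Can a head-and-neck treatment planner tell, *before* spending hours on a
helical-delivery (Tomotherapy-style) plan, whether a parotid gland can be
kept below its 26 Gy mean-dose sparing tolerance? This package implements an
overlap-volume answer to that question, aimed at medical physicists and
planners: the geometry of the contoured structures alone — how much of the
parotid lies inside the planning target volumes (PTVs) and their millimetre
expansions — predicts whether the achievable mean parotid dose will exceed
tolerance, so target volumes can be revised up front instead of after a
failed planning attempt.

## The model

For a parotid gland P and a target T, the **fractional overlap** is

    OLV(P, T) = |P ∩ T| / |P|

computed on a voxel grid in physical millimetres. The package computes the
standard family of predictors:

| statistic  | target                                             |
|------------|----------------------------------------------------|
| `OLV_CT`   | union of all PTV dose levels (combined PTV)        |
| `OLV_CT05` | combined PTV + 5 mm isotropic expansion            |
| `OLV_CT10` | combined PTV + 10 mm isotropic expansion           |
| `OLV_HD`   | highest-dose PTV                                   |
| `OLV_HD05` | highest-dose PTV + 5 mm expansion                  |
| `OLV_IM`, `OLV_LD` | intermediate- / lowest-dose PTV            |

A parotid is **positive** when its mean dose D_mean exceeds 26 Gy (equality
is negative). Parotids are stratified by which dose level they touch —
scenario A (high-dose PTV, gated on its 5 mm expansion by default), B
(intermediate only), C (low only) — and the shipped decision rule is:

* **Scenario A**: predict D_mean > 26 Gy iff `OLV_HD05` > 0.083
* **Scenario B**: predict exceedance iff `OLV_IM` ≥ 0.25
* **Scenario C / no overlap**: predict sparing

The calibration pipeline that produced that threshold is included:
ordinary least-squares regression of D_mean on each predictor, backward
stepwise model selection by AIC, ROC curves with strict-`>` thresholding,
and the Youden-optimal operating point. Isotropic expansion is a
millimetre-true Euclidean distance transform (compiled, anisotropic-voxel
aware), so a 5 mm margin means 5 mm regardless of grid spacing.

Because no clinical cohort ships with the package, a synthetic-cohort
generator produces whole plan bundles (nested ellipsoidal PTVs, bilateral
parotids of 11–55 cc, 2–4 prescription levels between 54 and 70 Gy, a dose
field with a 5 mm exponential falloff) whose noise-free mean-dose crossing
of 26 Gy was calibrated once to sit near `OLV_HD05` ≈ 0.083, giving every
statistical routine a ground-truthed test bed.

## Worked example

```r
library(ParotidOverlap)

params <- syntheticCohortParams(nPatients = 10, seed = 42)
gen <- generateCohort(params)

bundle <- gen$bundles[[1]]
bundle
#> PlanBundle 'plan001': 6 structure(s) [PTV_high, PTV_mid1, PTV_mid2,
#> PTV_low, parotid_left, parotid_right], dose present

masks <- structureMasks(bundle)
ptvs  <- masks[grep("^PTV", names(masks))]
rec <- computeRecord(masks$parotid_left, unname(ptvs), rxLevels(bundle),
                     dose = planDose(bundle), planId = planId(bundle))
round(rec[, c("OLV_HD", "OLV_HD05", "OLV_IM", "OLV_LD", "Dmean")], 4)
#>   OLV_HD OLV_HD05 OLV_IM OLV_LD   Dmean
#> 1      0        0 0.0661 0.1501 19.8681

predictExceeds(rec)
#>   scenario predictedExceeds drivingStat drivingValue note ruleVersion
#> 1        B            FALSE      OLV_IM   0.06608696       olv-rule-1
```

This parotid never touches the expanded high-dose PTV, overlaps the
intermediate level by 6.6% — well under the 25% scenario-B cutoff — and is
predicted spared; its actual mean dose in the synthetic plan is 19.9 Gy.

Recalibrating the rule on a study-sized cohort (37 plans, 74 parotids)
reproduces the decision threshold from the cohort itself:

```r
params <- syntheticCohortParams(nPatients = 37, seed = 1)
cohort <- generateCohort(params, keepBundles = FALSE)$cohort
cal <- calibrateRule(cohort)
cal$operatingPoint
#> OperatingPoint: threshold 0.08392 (sens 0.926, spec 1.000, J 0.926)
```

The calibrated threshold (0.0839) lands on the shipped clinical default
(0.083), and the AUC table in `cal$aucTable` shows the expanded high-dose
overlap discriminating better than the raw one — the model-selection
finding the rule is built on.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the full pipeline from scratch on a fresh synthetic cohort —
generation, the V100% ≥ 90% plan-inclusion filter, univariate and stepwise
regressions, ROC threshold calibration, AUC comparison of all five overlap
predictors, and per-parotid predictions — logging each stage and writing
the machine-readable result set as JSON to `--out`.
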