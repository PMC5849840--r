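test_that("dose levels rank per plan, not by absolute Gy", {
  expect_identical(assignDoseLevels(c(70, 59.4, 56)),
                   c("high", "intermediate", "low"))
  expect_identical(assignDoseLevels(c(60, 54)), c("high", "low"))
  expect_identical(assignDoseLevels(c(70, 66, 59.4, 56)),
                   c("high", "intermediate", "intermediate", "low"))
  expect_error(assignDoseLevels(c(56, 70)), "descending")
})

test_that("records compose overlap geometry correctly on a toy plan", {
  g <- VoxelGrid(c(40L, 26L, 26L), 1)
  occ <- array(FALSE, gridDims(g))
  occ[6:15, 9:18, 9:18] <- TRUE            # parotid: 10x10x10 cube
  par <- StructureMask(g, occ, "parotid")
  hocc <- array(FALSE, gridDims(g))
  hocc[16:25, 9:18, 9:18] <- TRUE          # high PTV cube, abutting
  hocc[15, 9:18, 9] <- TRUE                # sliver into the parotid: 10 voxels
  # overlap = 10 voxels of 1000
  hd <- StructureMask(g, hocc, "hd")
  ld <- expandMask(hd, 3); ld@name <- "ld"
  rec <- computeRecord(par, list(hd, ld), c(70, 56))
  expect_equal(rec$OLV_HD, 10 / 1000)
  bruteHD05 <- bruteExpand(occupancy(hd), c(1, 1, 1), 5)
  expect_equal(rec$OLV_HD05, sum(bruteHD05 & occupancy(par)) / 1000)
  expect_true(is.na(rec$OLV_IM))           # two-level plan
  expect_equal(rec$OLV_LD, rec$OLV_CT)     # nested union equals lowest level
  expect_true(is.na(rec$Dmean))            # no dose supplied

  # parotid fully inside the high-dose PTV: every overlap is 1
  inside <- computeRecord(StructureMask(g, hocc, "p2"), list(hd, ld),
                          c(70, 56))
  expect_true(all(inside[, c("OLV_CT", "OLV_CT05", "OLV_CT10", "OLV_HD",
                             "OLV_HD05", "OLV_LD")] == 1))
})

test_that("far-away parotids carry zero overlap everywhere", {
  g <- VoxelGrid(c(56L, 20L, 20L), 1)
  par <- ellipsoidMask(g, c(-20, 0, 0), c(5, 6, 7), "p")
  hd <- ellipsoidMask(g, c(19, 0, 0), c(4, 5, 6), "hd")  # > 10 mm + margins away
  im <- expandMask(hd, 2); ld <- expandMask(hd, 4)
  rec <- computeRecord(par, list(hd, im, ld), c(70, 63, 56))
  expect_true(all(rec[, c("OLV_CT", "OLV_CT05", "OLV_CT10", "OLV_HD",
                          "OLV_HD05", "OLV_IM", "OLV_LD")] == 0))
  expect_identical(assignScenario(rec), "none")
})

test_that("scenario assignment follows the A/B/C gate order", {
  expect_identical(assignScenario(recordRow(OLV_HD = 0.2, OLV_HD05 = 0.3),
                                  mode = "ptv"), "A")
  expect_identical(assignScenario(recordRow(OLV_HD = 0, OLV_IM = 0.1),
                                  mode = "ptv"), "B")
  expect_identical(assignScenario(recordRow(OLV_LD = 0.05), mode = "ptv"), "C")
  expect_identical(assignScenario(recordRow()), "none")
  # the expansion gate classifies grazing parotids as A even when OLV_HD = 0
  graze <- recordRow(OLV_HD = 0, OLV_HD05 = 0.02, OLV_IM = 0.1)
  expect_identical(assignScenario(graze, mode = "expansion"), "A")
  expect_identical(assignScenario(graze, mode = "ptv"), "B")
  # missing OLV_IM (two-level plan) counts as no overlap
  expect_identical(assignScenario(recordRow(OLV_IM = NA, OLV_LD = 0.1)), "C")
})

test_that("the decision rule reproduces all three branches", {
  cfg <- PredictionRuleConfig()
  # scenario A at 0.10 > 0.083: predicted to exceed tolerance
  pA <- predictExceeds(recordRow(OLV_HD05 = 0.10, OLV_IM = 0.1), cfg)
  expect_identical(pA$scenario, "A")
  expect_true(pA$predictedExceeds)
  expect_identical(pA$drivingStat, "OLV_HD05")
  # scenario A just at the threshold is negative (strict >)
  expect_false(predictExceeds(recordRow(OLV_HD05 = 0.083), cfg)$predictedExceeds)
  # scenario B at 0.10 < 0.25: sparing likely
  pB <- predictExceeds(recordRow(OLV_IM = 0.10), cfg)
  expect_identical(pB$scenario, "B")
  expect_false(pB$predictedExceeds)
  # scenario B at the observed exceedances (0.26, 0.34): positive
  expect_true(predictExceeds(recordRow(OLV_IM = 0.26), cfg)$predictedExceeds)
  expect_true(predictExceeds(recordRow(OLV_IM = 0.34), cfg)$predictedExceeds)
  # the boundary itself: positive but flagged indeterminate
  pBb <- predictExceeds(recordRow(OLV_IM = 0.25), cfg)
  expect_true(pBb$predictedExceeds)
  expect_match(pBb$note, "indeterminate")
  # scenario C (low-dose only, up to the observed maximum 0.16): negative
  for (v in c(0.01, 0.09, 0.16))
    expect_false(predictExceeds(recordRow(OLV_LD = v), cfg)$predictedExceeds)
  # no overlap: negative
  pN <- predictExceeds(recordRow(), cfg)
  expect_identical(pN$scenario, "none")
  expect_false(pN$predictedExceeds)
})

test_that("the rule is monotone in the scenario-A overlap", {
  cfg <- PredictionRuleConfig()
  vals <- seq(0.01, 0.5, by = 0.01)
  preds <- vapply(vals, function(v)
    predictExceeds(recordRow(OLV_HD05 = v), cfg)$predictedExceeds, logical(1))
  expect_true(all(diff(preds) >= 0))  # never flips positive -> negative
})

test_that("calibration recovers a perfect separator and reports exact counts", {
  set.seed(55)
  neg <- recordRow(OLV_HD05 = 0.02, Dmean = 20)
  cohort <- do.call(rbind, c(
    lapply(runif(20, 0.01, 0.07), function(v) recordRow(OLV_HD05 = v, Dmean = runif(1, 15, 24))),
    lapply(runif(20, 0.12, 0.4), function(v) recordRow(OLV_HD05 = v, Dmean = runif(1, 28, 45)))))
  cal <- calibrateRule(cohort)
  expect_equal(cal$sensitivity, 1.0)
  expect_equal(cal$specificity, 1.0)
  expect_gt(cal$config@thresholdHD05, 0.07)
  expect_lt(cal$config@thresholdHD05, 0.12)
  expect_equal(auc(cal$roc), 1.0)
  # sensitivity/specificity at the threshold equal direct confusion counts
  pos <- cohort$Dmean > 26
  pred <- cohort$OLV_HD05 > cal$config@thresholdHD05
  expect_identical(cal$sensitivity, sum(pred & pos) / sum(pos))
  expect_identical(cal$specificity, sum(!pred & !pos) / sum(!pos))

  allNeg <- do.call(rbind, lapply(runif(10, 0.05, 0.3), function(v)
    recordRow(OLV_HD05 = v, Dmean = 20)))
  expect_error(calibrateRule(allNeg), "both classes")
})

test_that("scenario-B candidate threshold is the class-gap midpoint", {
  rows <- list(
    recordRow(OLV_HD05 = 0.2, Dmean = 30),   # scenario A positive
    recordRow(OLV_HD05 = 0.02, Dmean = 20),  # scenario A negative
    recordRow(OLV_IM = 0.10, Dmean = 20),    # B negative
    recordRow(OLV_IM = 0.18, Dmean = 24),    # B negative
    recordRow(OLV_IM = 0.30, Dmean = 29))    # B positive
  cal <- calibrateRule(do.call(rbind, rows))
  expect_equal(cal$candidateThresholdIM, (0.18 + 0.30) / 2)
  expect_equal(cal$config@thresholdIM, 0.25)  # default is never overwritten
})

test_that("mirroring the geometry across the midline changes nothing", {
  set.seed(77)
  p <- syntheticCohortParams(nPatients = 1, seed = 77)
  pat <- generatePatient(p, "mirror")
  b <- pat$bundle
  flip <- function(a) a[dim(a)[1]:1, , , drop = FALSE]
  mmask <- function(m) StructureMask(m@grid, flip(occupancy(m)),
                                     structureName(m))
  masks <- structureMasks(b)
  ptvNames <- grep("^PTV", names(masks), value = TRUE)
  dose <- DoseGrid(planDose(b)@grid, flip(doseArray(planDose(b))))
  for (side in c("left", "right")) {
    par <- masks[[paste0("parotid_", side)]]
    recO <- computeRecord(par, unname(masks[ptvNames]), rxLevels(b),
                          dose = planDose(b))
    recM <- computeRecord(mmask(par), lapply(unname(masks[ptvNames]), mmask),
                          rxLevels(b), dose = dose)
    olv <- c("OLV_CT", "OLV_CT05", "OLV_CT10", "OLV_HD", "OLV_HD05",
             "OLV_IM", "OLV_LD")
    expect_equal(recM[, olv], recO[, olv])
    expect_equal(recM$Dmean, recO$Dmean)
    expect_identical(assignScenario(recM), assignScenario(recO))
    expect_identical(predictExceeds(recM)$predictedExceeds,
                     predictExceeds(recO)$predictedExceeds)
  }
})
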