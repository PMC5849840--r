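## Scenario assignment by dose level and the threshold decision rule
## predicting parotid D_mean > 26 Gy, plus rule calibration on a cohort.

.ruleVersion <- "olv-rule-1"

#' Rank a plan's prescription levels into high / intermediate / low
#'
#' Dose-level ranking is the per-plan relative rank of the prescriptions,
#' not absolute Gy bands: the highest level is "high", the lowest "low",
#' and anything between "intermediate". A two-level plan therefore has no
#' intermediate level. Relative ranking resolves every clinically common
#' prescription scheme unambiguously, including those where a 60 Gy level is
#' intermediate in one scheme and low in another.
#'
#' @param rxLevels numeric prescriptions in Gy, strictly descending (2-4)
#' @return character vector parallel to \code{rxLevels} with values
#'   "high", "intermediate", "low"
#' @examples
#' assignDoseLevels(c(70, 59.4, 56))
#' @export
assignDoseLevels <- function(rxLevels) {
  nl <- length(rxLevels)
  if (nl < 2L || nl > 4L || any(diff(rxLevels) >= 0))
    stop("rxLevels must be 2-4 strictly descending prescriptions")
  c("high", rep("intermediate", nl - 2L), "low")
}

#' Compute one parotid's overlap record
#'
#' Fills every fractional-overlap statistic for one parotid against a plan's
#' PTV set: OLV_CT / OLV_CT05 / OLV_CT10 against the union of all PTVs and
#' its 5 / 10 mm isotropic expansions; OLV_HD / OLV_HD05 against the
#' highest-dose PTV and its 5 mm expansion; OLV_IM and OLV_LD against the
#' intermediate-level PTV(s) (their union when a four-level plan has two)
#' and the lowest-level PTV. When a dose grid is supplied, D_mean and the
#' positivity label (D_mean strictly greater than the tolerance; equality is
#' negative) are filled as well. A two-level plan has no intermediate level;
#' its OLV_IM is NA.
#'
#' @param parotid nonempty \linkS4class{StructureMask}
#' @param ptvs list of \linkS4class{StructureMask}, one per prescription
#'   level, ordered like \code{rxLevels} (highest first), sharing the
#'   parotid's grid
#' @param rxLevels prescriptions in Gy, strictly descending
#' @param dose optional \linkS4class{DoseGrid}
#' @param config a \linkS4class{PredictionRuleConfig} (supplies the
#'   tolerance and the high-dose expansion margin)
#' @param planId,side identifiers carried into the record
#' @return one-row data.frame (a parotid record) with columns planId, side,
#'   parotidVolumeCC, OLV_CT, OLV_CT05, OLV_CT10, OLV_HD, OLV_HD05, OLV_IM,
#'   OLV_LD, Dmean, positive
#' @export
computeRecord <- function(parotid, ptvs, rxLevels, dose = NULL,
                          config = PredictionRuleConfig(),
                          planId = "plan", side = "left") {
  stopifnot(is(parotid, "StructureMask"), length(ptvs) == length(rxLevels))
  lev <- assignDoseLevels(rxLevels)
  ct <- unionMasks(ptvs)
  hd <- ptvs[[1L]]
  im <- if (any(lev == "intermediate"))
    unionMasks(ptvs[lev == "intermediate"]) else NULL
  ld <- ptvs[[length(ptvs)]]
  rec <- data.frame(
    planId = planId, side = side,
    parotidVolumeCC = volumeCC(parotid),
    OLV_CT = fractionalOverlap(parotid, ct),
    OLV_CT05 = fractionalOverlap(parotid, expandMask(ct, 5)),
    OLV_CT10 = fractionalOverlap(parotid, expandMask(ct, 10)),
    OLV_HD = fractionalOverlap(parotid, hd),
    OLV_HD05 = fractionalOverlap(parotid,
                                 expandMask(hd, config@hdMarginMm)),
    OLV_IM = if (is.null(im)) NA_real_ else fractionalOverlap(parotid, im),
    OLV_LD = fractionalOverlap(parotid, ld),
    Dmean = NA_real_, positive = NA,
    stringsAsFactors = FALSE)
  if (!is.null(dose)) {
    rec$Dmean <- meanDose(dose, parotid)
    rec$positive <- rec$Dmean > config@toleranceGy
  }
  rec
}

.olv <- function(record, field) {
  v <- record[[field]]
  if (is.null(v) || is.na(v)) 0 else v
}

#' Assign the overlap scenario of a parotid record
#'
#' Scenario "A": the parotid overlaps the high-dose PTV — gated on the 5 mm
#' expansion (OLV_HD05 > 0) in mode "expansion" (the decision rule's gate),
#' or on the raw PTV (OLV_HD > 0) in mode "ptv" (the stratification used
#' when plotting dose against per-level overlap). Otherwise "B" when the
#' parotid overlaps an intermediate-dose PTV, otherwise "C" when it overlaps
#' the low-dose PTV, otherwise "none". A missing OLV (e.g. OLV_IM on a
#' two-level plan) counts as no overlap.
#'
#' @param record one-row parotid record (see \code{\link{computeRecord}})
#' @param mode "expansion" (default) or "ptv"
#' @return one of "A", "B", "C", "none"
#' @export
assignScenario <- function(record, mode = c("expansion", "ptv")) {
  mode <- match.arg(mode)
  gate <- if (mode == "expansion") .olv(record, "OLV_HD05")
          else .olv(record, "OLV_HD")
  if (gate > 0) "A"
  else if (.olv(record, "OLV_IM") > 0) "B"
  else if (.olv(record, "OLV_LD") > 0) "C"
  else "none"
}

#' Predict whether a parotid's mean dose will exceed tolerance
#'
#' The three-branch rule: a scenario-A parotid (overlapping the expanded
#' high-dose PTV) is predicted to exceed the tolerance when OLV_HD05 is
#' strictly greater than \code{config@thresholdHD05} (default 0.083); a
#' scenario-B parotid (intermediate overlap only) when OLV_IM is at least
#' \code{config@thresholdIM} (default 0.25) — sparing is likely below 25%,
#' and the observed exceedances sat just above it, so the boundary itself is
#' called positive but flagged indeterminate; scenario C (low-dose overlap
#' only) and no overlap are always predicted spared.
#'
#' @param record one-row parotid record
#' @param config a \linkS4class{PredictionRuleConfig}
#' @return one-row data.frame: scenario, predictedExceeds, drivingStat,
#'   drivingValue, note, ruleVersion
#' @export
predictExceeds <- function(record, config = PredictionRuleConfig()) {
  sc <- assignScenario(record, mode = config@groupingMode)
  note <- ""
  if (sc == "A") {
    v <- record[["OLV_HD05"]]
    if (is.null(v) || is.na(v))
      stop("scenario A requires OLV_HD05, which is missing from the record")
    pos <- v > config@thresholdHD05
    stat <- "OLV_HD05"
  } else if (sc == "B") {
    v <- record[["OLV_IM"]]
    if (is.null(v) || is.na(v))
      stop("scenario B requires OLV_IM, which is missing from the record")
    pos <- v >= config@thresholdIM
    stat <- "OLV_IM"
    if (isTRUE(all.equal(v, config@thresholdIM)))
      note <- "indeterminate: overlap sits exactly at the scenario-B cutoff"
  } else if (sc == "C") {
    v <- .olv(record, "OLV_LD")
    pos <- FALSE
    stat <- "OLV_LD"
    note <- "low-dose overlap only: mean dose is likely under tolerance"
  } else {
    v <- 0
    pos <- FALSE
    stat <- "none"
    note <- "no PTV overlap"
  }
  data.frame(scenario = sc, predictedExceeds = pos, drivingStat = stat,
             drivingValue = v, note = note, ruleVersion = .ruleVersion,
             stringsAsFactors = FALSE)
}

#' Calibrate the decision rule on a cohort of parotid records
#'
#' Restricts the cohort to scenario-A records (per the config's grouping
#' mode), builds the ROC of OLV_HD05 against the observed positivity
#' (D_mean above tolerance), and sets the scenario-A threshold from the
#' optimal operating point. Reports the AUC of every overlap predictor side
#' by side — the high-dose family on the scenario-A subset, the
#' combined-target family on the full cohort, mirroring how the two model
#' families were originally compared. The scenario-B threshold is left at
#' its default; when scenario-B positives exist, the midpoint between the
#' largest negative and smallest positive OLV_IM is reported as a candidate.
#' The returned config never silently replaces the shipped defaults: callers
#' opt in by using it.
#'
#' @param cohort data.frame of parotid records (rows as from
#'   \code{\link{computeRecord}}, with Dmean filled)
#' @param config baseline \linkS4class{PredictionRuleConfig}
#' @param criterion operating-point criterion, see
#'   \code{\link{optimalOperatingPoint}}
#' @return list with elements \code{config} (recalibrated), \code{roc}
#'   (\linkS4class{RocCurve} of OLV_HD05 on scenario A),
#'   \code{operatingPoint}, \code{sensitivity}, \code{specificity},
#'   \code{aucTable} (data.frame: predictor, subset, n, auc),
#'   \code{candidateThresholdIM}, \code{nScenarioA}
#' @export
calibrateRule <- function(cohort, config = PredictionRuleConfig(),
                          criterion = "youden") {
  stopifnot(is.data.frame(cohort), all(c("OLV_HD05", "Dmean") %in%
                                         names(cohort)))
  pos <- cohort$Dmean > config@toleranceGy
  scen <- vapply(seq_len(nrow(cohort)), function(i)
    assignScenario(cohort[i, ], mode = config@groupingMode), character(1))
  a <- which(scen == "A")
  nPos <- sum(pos[a])
  nNeg <- sum(!pos[a])
  if (nPos == 0L || nNeg == 0L)
    stop(sprintf(
      paste0("calibration needs scenario-A records of both classes; got ",
             "%d above and %d at-or-below tolerance among %d scenario-A ",
             "records"), nPos, nNeg, length(a)))
  rc <- rocCurve(cohort$OLV_HD05[a], pos[a])
  op <- optimalOperatingPoint(rc, criterion = criterion)
  predPos <- cohort$OLV_HD05[a] > op@threshold
  sens <- sum(predPos & pos[a]) / nPos
  spec <- sum(!predPos & !pos[a]) / nNeg
  aucRow <- function(pred, idx, subset) {
    ok <- idx[!is.na(cohort[[pred]][idx])]
    val <- if (length(unique(pos[ok])) == 2L)
      rocCurve(cohort[[pred]][ok], pos[ok])@auc else NA_real_
    data.frame(predictor = pred, subset = subset, n = length(ok), auc = val,
               stringsAsFactors = FALSE)
  }
  aucTable <- rbind(
    aucRow("OLV_HD", a, "scenario A"),
    aucRow("OLV_HD05", a, "scenario A"),
    aucRow("OLV_CT", seq_len(nrow(cohort)), "all records"),
    aucRow("OLV_CT05", seq_len(nrow(cohort)), "all records"),
    aucRow("OLV_CT10", seq_len(nrow(cohort)), "all records"))
  candIM <- NA_real_
  b <- which(scen == "B" & !is.na(cohort$OLV_IM))
  if (length(b) && any(pos[b]) && any(!pos[b]))
    candIM <- (max(cohort$OLV_IM[b][!pos[b]]) +
                 min(cohort$OLV_IM[b][pos[b]])) / 2
  newConfig <- config
  newConfig@thresholdHD05 <- op@threshold
  validObject(newConfig)
  list(config = newConfig, roc = rc, operatingPoint = op,
       sensitivity = sens, specificity = spec, aucTable = aucTable,
       candidateThresholdIM = candIM, nScenarioA = length(a))
}
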