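## Synthetic plan-cohort generator.
##
## Emulates a head-and-neck helical-delivery cohort: two ellipsoidal
## parotids placed laterally, 2-4 nested PTV dose levels built by expanding
## the high-dose shape, and a dose field with a steep exponential distance
## falloff (inside-PTV dose equals the prescription), so that parotid mean
## dose rises monotonically with overlap fraction and crosses the 26 Gy
## tolerance near small overlaps with the expanded high-dose target. All
## overlap statistics in the emitted tables are recomputed with the
## package's own geometry on the emitted masks, so the generator is exactly
## self-consistent with the analysis path.

#' SyntheticCohortParams: the stated world of the synthetic cohort
#'
#' Defaults encode the cohort the analysis assumes: bilateral parotids with
#' volumes spanning 11.35-55.18 cc, prescription schemes drawn from the
#' clinically observed menu (54-70 Gy, 2-4 levels) with their observed case
#' weights, a 5 mm dose falloff length matching the delivery's effective
#' field size, and 1.5 Gy of per-parotid mean-dose scatter. The nested-level
#' expansion steps (high to intermediate, then per further level) were
#' calibrated once so the noise-free mean-dose crossing of the tolerance
#' sits at a fractional high-dose-expansion overlap of 0.083.
#'
#' @slot nPatients number of patients (2 parotids each)
#' @slot seed RNG seed used by \code{\link{generateCohort}}
#' @slot parotidVolumeRangeCC sampled parotid volume range, cc
#' @slot rxMenu list of prescription schemes (Gy, descending)
#' @slot rxWeights sampling weight per scheme
#' @slot scenarioMix named probabilities for placement targets A/B/C/none
#' @slot overlapRangeA sampled target overlap (with the 5 mm-expanded
#'   high-dose PTV) for scenario-A placements
#' @slot imStepRangeMm sampled expansion step from the high-dose PTV to the
#'   next level, mm
#' @slot lowStepRangeMm sampled expansion step per further level, mm
#' @slot ptvSemiAxesMm base semi-axes of the high-dose PTV, mm
#' @slot ptvJitterFrac relative jitter applied to the PTV semi-axes
#' @slot falloffLambdaMm dose falloff length lambda, mm
#' @slot noiseSdGy sd of the per-parotid mean-dose perturbation, Gy
#' @slot spacingMm grid spacing, mm
#' @slot gridDims grid dimensions (voxels)
#' @slot dropoutProb probability that a plan's recorded V100\% simulates
#'   unacceptable coverage (exercises the plan-inclusion filter)
#' @export
setClass("SyntheticCohortParams",
  representation(nPatients = "integer", seed = "integer",
                 parotidVolumeRangeCC = "numeric", rxMenu = "list",
                 rxWeights = "numeric", scenarioMix = "numeric",
                 overlapRangeA = "numeric", imStepRangeMm = "numeric",
                 lowStepRangeMm = "numeric", ptvSemiAxesMm = "numeric",
                 ptvJitterFrac = "numeric", falloffLambdaMm = "numeric",
                 noiseSdGy = "numeric", spacingMm = "numeric",
                 gridDims = "integer", dropoutProb = "numeric"))

setValidity("SyntheticCohortParams", function(object) {
  msg <- character()
  if (object@nPatients < 1L) msg <- c(msg, "nPatients must be >= 1")
  if (object@falloffLambdaMm <= 0) msg <- c(msg, "lambda must be > 0")
  if (object@noiseSdGy < 0) msg <- c(msg, "noiseSdGy must be >= 0")
  if (length(object@parotidVolumeRangeCC) != 2L ||
      any(object@parotidVolumeRangeCC <= 0) ||
      diff(object@parotidVolumeRangeCC) <= 0)
    msg <- c(msg, "parotidVolumeRangeCC must be a positive ordered pair")
  if (length(object@rxMenu) != length(object@rxWeights))
    msg <- c(msg, "rxMenu and rxWeights must have equal length")
  if (!all(c("A", "B", "C", "none") %in% names(object@scenarioMix)))
    msg <- c(msg, "scenarioMix needs probabilities for A, B, C, none")
  if (length(msg)) msg else TRUE
})

## the clinically observed prescription menu with per-scheme case counts
.rxMenuDefault <- list(
  c(70, 66, 59.4, 56), c(69.96, 66, 59.4, 54.45), c(70, 63, 56),
  c(70, 59.4, 56), c(69.96, 59.4, 54.45), c(66, 59.4, 56),
  c(66, 60, 54.45), c(69.96, 59.4), c(66, 54), c(60, 54))
.rxWeightsDefault <- c(2, 1, 5, 14, 5, 2, 8, 1, 2, 3)

#' Construct SyntheticCohortParams
#'
#' @param nPatients number of patients
#' @param seed RNG seed
#' @param parotidVolumeRangeCC cc range of parotid volumes
#' @param rxMenu,rxWeights prescription schemes and sampling weights
#' @param scenarioMix named A/B/C/none placement probabilities
#' @param overlapRangeA target overlap range for scenario-A placements
#' @param imStepRangeMm,lowStepRangeMm nested-level expansion steps, mm
#' @param ptvSemiAxesMm,ptvJitterFrac high-dose PTV shape and jitter
#' @param falloffLambdaMm dose falloff length, mm
#' @param noiseSdGy per-parotid mean-dose noise sd, Gy
#' @param spacingMm,gridDims voxel grid geometry
#' @param dropoutProb probability of a simulated coverage failure
#' @return a \linkS4class{SyntheticCohortParams}
#' @export
syntheticCohortParams <- function(nPatients = 37L, seed = 1L,
                                  parotidVolumeRangeCC = c(11.35, 55.18),
                                  rxMenu = .rxMenuDefault,
                                  rxWeights = .rxWeightsDefault,
                                  scenarioMix = c(A = 0.35, B = 0.20,
                                                  C = 0.25, none = 0.20),
                                  overlapRangeA = c(0.005, 0.40),
                                  imStepRangeMm = c(6, 8),
                                  lowStepRangeMm = c(2.7, 3.7),
                                  ptvSemiAxesMm = c(22, 26, 25),
                                  ptvJitterFrac = 0.15,
                                  falloffLambdaMm = 5,
                                  noiseSdGy = 1.5,
                                  spacingMm = c(2, 2, 2),
                                  gridDims = c(96L, 72L, 56L),
                                  dropoutProb = 0.05) {
  new("SyntheticCohortParams", nPatients = as.integer(nPatients),
      seed = as.integer(seed),
      parotidVolumeRangeCC = parotidVolumeRangeCC, rxMenu = rxMenu,
      rxWeights = rxWeights, scenarioMix = scenarioMix,
      overlapRangeA = overlapRangeA, imStepRangeMm = imStepRangeMm,
      lowStepRangeMm = lowStepRangeMm, ptvSemiAxesMm = ptvSemiAxesMm,
      ptvJitterFrac = ptvJitterFrac, falloffLambdaMm = falloffLambdaMm,
      noiseSdGy = noiseSdGy, spacingMm = rep_len(spacingMm, 3L),
      gridDims = as.integer(gridDims), dropoutProb = dropoutProb)
}

setMethod("show", "SyntheticCohortParams", function(object) {
  cat(sprintf(
    paste0("SyntheticCohortParams: %d patients, lambda %g mm, noise %g Gy,",
           " grid %s @ %s mm\n"),
    object@nPatients, object@falloffLambdaMm, object@noiseSdGy,
    paste(object@gridDims, collapse = "x"),
    paste(object@spacingMm, collapse = "/")))
})

## linear indices (ascending) of voxels whose centers lie inside the
## axis-aligned ellipsoid; errors if the ellipsoid collides with the grid
.ellipsoidIndices <- function(grid, center, semi, clip = FALSE) {
  xs <- axisCenters(grid, 1L); ys <- axisCenters(grid, 2L)
  zs <- axisCenters(grid, 3L)
  if (!clip) {
    lo <- c(xs[1L], ys[1L], zs[1L]); hi <- c(max(xs), max(ys), max(zs))
    if (any(center - semi < lo) || any(center + semi > hi))
      stop(sprintf(
        "structure at (%s) mm with semi-axes (%s) mm collides with the grid boundary",
        paste(format(center), collapse = ", "),
        paste(format(semi), collapse = ", ")))
  }
  ix <- which(abs(xs - center[1L]) <= semi[1L])
  iy <- which(abs(ys - center[2L]) <= semi[2L])
  iz <- which(abs(zs - center[3L]) <= semi[3L])
  if (!length(ix) || !length(iy) || !length(iz)) return(integer(0))
  ux <- ((xs[ix] - center[1L]) / semi[1L])^2
  uy <- ((ys[iy] - center[2L]) / semi[2L])^2
  uz <- ((zs[iz] - center[3L]) / semi[3L])^2
  sxy <- outer(ux, uy, "+")
  nx <- grid@dims[1L]
  nxy <- nx * grid@dims[2L]
  bxy <- outer(ix - 1L, (iy - 1L) * nx, "+")
  out <- vector("list", length(iz))
  for (k in seq_along(iz)) {
    sel <- sxy <= 1 - uz[k]
    out[[k]] <- bxy[sel] + nxy * (iz[k] - 1L) + 1L
  }
  unlist(out)
}

#' Rasterize an axis-aligned ellipsoid onto a grid
#'
#' Voxel centers inside \eqn{\sum_k ((x_k - c_k)/a_k)^2 \le 1} are occupied.
#' Analytic volume \eqn{(4/3)\pi a b c} makes these masks free oracles for
#' volume checks.
#'
#' @param grid a \linkS4class{VoxelGrid}
#' @param center mm center (x, y, z)
#' @param semiAxesMm mm semi-axes (a, b, c)
#' @param name structure label
#' @return a \linkS4class{StructureMask}
#' @export
ellipsoidMask <- function(grid, center, semiAxesMm, name = "ellipsoid") {
  occ <- array(FALSE, dim = grid@dims)
  occ[.ellipsoidIndices(grid, center, semiAxesMm, clip = TRUE)] <- TRUE
  StructureMask(grid, occ, name = name)
}

## fraction of the ellipsoid's voxels whose distance map value is <= thr
.overlapAt <- function(dmap, grid, center, semi, thr) {
  idx <- .ellipsoidIndices(grid, center, semi, clip = TRUE)
  if (!length(idx)) return(0)
  mean(dmap[idx] <= thr)
}

## bisection on the lateral center position: returns the xc (within [lo,
## hi], sign applied by the caller) whose overlap fraction best approaches
## the target u; f(xc) is non-increasing in xc
.solveLateral <- function(dmap, grid, yc, zc, semi, thr, u, lo, hi,
                          iter = 24L) {
  fl <- .overlapAt(dmap, grid, c(lo, yc, zc), semi, thr)
  fh <- .overlapAt(dmap, grid, c(hi, yc, zc), semi, thr)
  if (fl <= u) return(lo)
  if (fh >= u) return(hi)
  for (i in seq_len(iter)) {
    mid <- (lo + hi) / 2
    fm <- .overlapAt(dmap, grid, c(mid, yc, zc), semi, thr)
    if (fm >= u) { lo <- mid; fl <- fm } else { hi <- mid; fh <- fm }
  }
  if (abs(fl - u) <= abs(fh - u)) lo else hi
}

## smallest lateral position at which the overlap at threshold thr vanishes
.solveClear <- function(dmap, grid, yc, zc, semi, thr, lo, hi, iter = 24L) {
  if (.overlapAt(dmap, grid, c(lo, yc, zc), semi, thr) == 0) return(lo)
  for (i in seq_len(iter)) {
    mid <- (lo + hi) / 2
    if (.overlapAt(dmap, grid, c(mid, yc, zc), semi, thr) > 0) lo <- mid
    else hi <- mid
  }
  hi
}

## dose field from the high-dose distance map: level l's bath covers the
## high-dose PTV expanded by its cumulative margin and decays exponentially
## beyond it
.doseFromDistance <- function(dH, rxLevels, cumMarginsMm, lambdaMm) {
  dose <- rxLevels[1L] * exp(-dH / lambdaMm)
  for (l in seq_along(rxLevels)[-1L]) {
    dose <- pmax(dose, rxLevels[l] *
                   exp(-pmax(dH - cumMarginsMm[l - 1L], 0) / lambdaMm))
  }
  dose
}

#' Synthesize a steep-gradient dose field around a nested PTV set
#'
#' The dose model of the synthetic cohort:
#' \deqn{D(x) = \max_l Rx_l \exp(-\max(0, d_H(x) - m_l)/\lambda)}
#' where \eqn{d_H} is the Euclidean distance to the high-dose PTV and
#' \eqn{m_l} the cumulative expansion margin of level l (\eqn{m_1 = 0}).
#' Every voxel of a level's PTV receives at least that level's
#' prescription (the high-dose PTV exactly its prescription), and the dose
#' beyond each target falls off exponentially with length \code{lambdaMm},
#' emulating a helical delivery's steep gradients. Enlarging any margin
#' never decreases the dose anywhere.
#'
#' @param hd the high-dose PTV \linkS4class{StructureMask}
#' @param rxLevels prescriptions in Gy, strictly descending
#' @param marginsMm cumulative expansion margins (mm) of levels 2..L
#'   (length \code{length(rxLevels) - 1}, increasing)
#' @param lambdaMm falloff length in mm
#' @return a \linkS4class{DoseGrid} on the mask's grid
#' @export
synthesizeDose <- function(hd, rxLevels, marginsMm, lambdaMm = 5) {
  stopifnot(is(hd, "StructureMask"),
            length(marginsMm) == length(rxLevels) - 1L,
            all(diff(c(0, marginsMm)) > 0), lambdaMm > 0)
  dH <- distanceTransform(hd)
  DoseGrid(hd@grid, .doseFromDistance(dH, rxLevels, marginsMm, lambdaMm))
}

#' Generate one synthetic patient plan
#'
#' Consumes the current RNG state (use \code{\link{generateCohort}} for
#' seeded, reproducible cohorts). Builds the nested PTV set, places both
#' parotids according to sampled scenario targets, synthesizes the dose
#' field \eqn{D(x) = \max_l Rx_l \exp(-d(x, PTV_l)/\lambda)} (so the dose
#' inside each PTV equals its prescription), perturbs each parotid's dose by
#' one Gaussian draw, and assembles the plan bundle plus ground truth.
#'
#' @param params a \linkS4class{SyntheticCohortParams}
#' @param planId plan identifier
#' @return list with \code{bundle} (a \linkS4class{PlanBundle}),
#'   \code{records} (2-row cohort data.frame, one per parotid) and
#'   \code{truth} (2-row ground-truth data.frame with noise-free and noisy
#'   mean doses and the placement targets)
#' @export
generatePatient <- function(params, planId = "plan1") {
  grid <- VoxelGrid(params@gridDims, params@spacingMm)
  lambda <- params@falloffLambdaMm
  rx <- params@rxMenu[[sample.int(length(params@rxMenu), 1L,
                                  prob = params@rxWeights)]]
  L <- length(rx)
  ## nested-level expansion margins (cumulative, mm beyond the high PTV)
  steps <- c(stats::runif(1L, params@imStepRangeMm[1L],
                          params@imStepRangeMm[2L]),
             stats::runif(L, params@lowStepRangeMm[1L],
                          params@lowStepRangeMm[2L]))
  cum <- cumsum(steps)[seq_len(L - 1L)]
  if (L == 2L) cum <- sum(steps[1:2])  # single lower level is the elective one
  ## high-dose PTV near the midline
  jit <- function(n, w) stats::runif(n, 1 - w, 1 + w)
  ptvSemi <- params@ptvSemiAxesMm * jit(3L, params@ptvJitterFrac)
  ptvCenter <- c(0, stats::runif(1L, -6, 6), stats::runif(1L, -4, 4))
  hd <- ellipsoidMask(grid, ptvCenter, ptvSemi, name = "PTV_high")
  dH <- distanceTransform(hd)
  levelNames <- c("PTV_high",
                  if (L > 2L) paste0("PTV_mid", seq_len(L - 2L)),
                  "PTV_low")[seq_len(L)]
  masks <- list(hd)
  for (l in seq_len(L - 1L)) {
    masks[[l + 1L]] <- StructureMask(grid, dH <= cum[l],
                                     name = levelNames[l + 1L])
  }
  names(masks) <- levelNames
  cmIM <- if (L > 2L) cum[L - 2L] else NA_real_
  cmL <- cum[L - 1L]
  ## dose: steep exponential falloff, each level's bath reaching its margin
  dose <- .doseFromDistance(dH, rx, cum, lambda)
  ## distance map of the lowest level (= combined PTV), for its expansions
  dLow <- distanceTransform(masks[[L]])
  trueDose <- dose

  xsMax <- max(axisCenters(grid, 1L))
  records <- NULL
  truth <- NULL
  parotids <- list()
  placement <- list()
  for (side in c("left", "right")) {
    sgn <- if (side == "left") 1 else -1
    vol <- stats::runif(1L, params@parotidVolumeRangeCC[1L] + 0.8,
                        params@parotidVolumeRangeCC[2L] - 2.5)
    ry <- stats::runif(1L, 1.2, 1.6)
    rz <- stats::runif(1L, 1.6, 2.2)
    a <- (3000 * vol / (4 * pi * ry * rz))^(1 / 3)
    semi <- c(a, a * ry, a * rz)
    yc <- ptvCenter[2L] + stats::runif(1L, -8, 8)
    zc <- ptvCenter[3L] + stats::runif(1L, -6, 6)
    scn <- sample(names(params@scenarioMix), 1L,
                  prob = params@scenarioMix)
    if (scn == "B" && L == 2L) scn <- "C"  # no intermediate level to overlap
    hi <- xsMax - semi[1L] - 1
    xc <- if (scn == "A") {
      u <- stats::runif(1L, params@overlapRangeA[1L],
                        params@overlapRangeA[2L])
      .solveLateral(dH, grid, yc, zc, semi, 5, u, lo = 0, hi = hi)
    } else if (scn == "B") {
      xb <- .solveClear(dH, grid, yc, zc, semi, 5, lo = 0, hi = hi)
      uMax <- .overlapAt(dH, grid, c(xb, yc, zc), semi, cmIM)
      u <- min(stats::runif(1L, 0.02, 0.45), uMax)
      .solveLateral(dH, grid, yc, zc, semi, cmIM, u, lo = xb, hi = hi)
    } else if (scn == "C") {
      thrClear <- if (L > 2L) cmIM else 5
      xb <- .solveClear(dH, grid, yc, zc, semi, thrClear, lo = 0, hi = hi)
      uMax <- .overlapAt(dH, grid, c(xb, yc, zc), semi, cmL)
      u <- min(stats::runif(1L, 0.01, 0.16), uMax)
      .solveLateral(dH, grid, yc, zc, semi, cmL, u, lo = xb, hi = hi)
    } else {
      .solveClear(dH, grid, yc, zc, semi, cmL + 12, lo = 0, hi = hi)
    }
    center <- c(sgn * xc, yc, zc)
    idx <- .ellipsoidIndices(grid, center, semi)
    if (!length(idx))
      stop("degenerate parotid placement for plan ", planId)
    nm <- paste0("parotid_", side)
    occ <- array(FALSE, dim = grid@dims)
    occ[idx] <- TRUE
    parotids[[nm]] <- StructureMask(grid, occ, name = nm)
    placement[[side]] <- list(idx = idx, scn = scn)
  }
  ## one Gaussian perturbation per parotid's mean dose, applied before any
  ## tabulation so records agree with the emitted grid even if the glands
  ## share voxels
  for (side in names(placement)) {
    delta <- stats::rnorm(1L, 0, params@noiseSdGy)
    idx <- placement[[side]]$idx
    dose[idx] <- pmax(dose[idx] + delta, 0)
  }
  for (side in names(placement)) {
    idx <- placement[[side]]$idx
    scn <- placement[[side]]$scn
    np <- length(idx)
    rec <- data.frame(
      planId = planId, side = side,
      parotidVolumeCC = np * voxelVolumeMm3(grid) / 1000,
      OLV_CT = mean(dH[idx] <= cmL),
      OLV_CT05 = mean(dLow[idx] <= 5),
      OLV_CT10 = mean(dLow[idx] <= 10),
      OLV_HD = mean(dH[idx] <= 0),
      OLV_HD05 = mean(dH[idx] <= 5),
      OLV_IM = if (L > 2L) mean(dH[idx] <= cmIM) else NA_real_,
      OLV_LD = mean(dH[idx] <= cmL),
      Dmean = mean(dose[idx]), positive = NA,
      stringsAsFactors = FALSE)
    rec$positive <- rec$Dmean > 26
    records <- rbind(records, rec)
    truth <- rbind(truth, data.frame(
      planId = planId, side = side, placementTarget = scn,
      trueDmean = mean(trueDose[idx]), noisyDmean = rec$Dmean,
      truePositive = mean(trueDose[idx]) > 26,
      stringsAsFactors = FALSE))
  }
  ## recorded coverage: computed from the dose grid, except for simulated
  ## coverage failures (metadata-level, to exercise the inclusion filter)
  doseGrid <- DoseGrid(grid, dose)
  v100 <- if (stats::runif(1L) < params@dropoutProb)
    stats::runif(1L, 0.80, 0.895)
  else coverageFraction(doseGrid, hd, rx[1L])
  meta <- PlanMeta(planId, rx, v100 = v100,
                   delivery = paste("synthetic helical delivery:",
                                    "field 2.5 cm, pitch 0.215, MF 3.5"))
  bundle <- PlanBundle(c(masks, parotids), dose = doseGrid, meta = meta)
  rownames(records) <- NULL
  rownames(truth) <- NULL
  list(bundle = bundle, records = records, truth = truth)
}

#' Generate a synthetic cohort of plans
#'
#' Seeds the RNG from \code{params@seed} and generates
#' \code{params@nPatients} patients with two parotids each, returning the
#' cohort table consumed by \code{\link{calibrateRule}} together with the
#' ground truth. Identical params give bit-identical output.
#'
#' @param params a \linkS4class{SyntheticCohortParams}
#' @param keepBundles keep every \linkS4class{PlanBundle} in memory (TRUE,
#'   default) or drop them after tabulation (FALSE; large cohorts)
#' @return list with \code{bundles} (list of PlanBundle or NULL),
#'   \code{cohort} (parotid-record data.frame, one row per parotid) and
#'   \code{truth} (ground-truth data.frame)
#' @export
generateCohort <- function(params, keepBundles = TRUE) {
  set.seed(params@seed)
  bundles <- if (keepBundles) vector("list", params@nPatients) else NULL
  recs <- vector("list", params@nPatients)
  truths <- vector("list", params@nPatients)
  for (i in seq_len(params@nPatients)) {
    pid <- sprintf("plan%03d", i)
    p <- generatePatient(params, planId = pid)
    if (keepBundles) bundles[[i]] <- p$bundle
    recs[[i]] <- p$records
    truths[[i]] <- p$truth
  }
  list(bundles = bundles,
       cohort = do.call(rbind, recs),
       truth = do.call(rbind, truths))
}
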