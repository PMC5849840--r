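## Mean-dose / coverage statistics and the plan-inclusion filter.

## Trilinear sampling of a dose grid at arbitrary physical points (n x 3 mm).
## Errors if any point falls outside the dose grid's bounding box (the box
## spanned by the outermost voxel centers).
.sampleDose <- function(d, pts) {
  g <- d@grid
  tol <- 1e-9
  t <- sweep(sweep(pts, 2L, g@origin, "-"), 2L, g@spacing, "/")
  hi <- g@dims - 1L
  bad <- which(t[, 1L] < -tol | t[, 1L] > hi[1L] + tol |
               t[, 2L] < -tol | t[, 2L] > hi[2L] + tol |
               t[, 3L] < -tol | t[, 3L] > hi[3L] + tol)
  if (length(bad))
    stop(sprintf(
      "%d structure voxel center(s) lie outside the dose grid; first at (%s) mm",
      length(bad), paste(format(pts[bad[1L], ]), collapse = ", ")))
  t <- pmin(pmax(t, 0), matrix(hi, nrow(t), 3L, byrow = TRUE))
  i0 <- pmin(floor(t), matrix(hi - 1L, nrow(t), 3L, byrow = TRUE))
  i0[i0 < 0] <- 0L
  fr <- t - i0
  nx <- g@dims[1L]; nxy <- g@dims[1L] * g@dims[2L]
  at <- function(dx, dy, dz) {
    idx <- (i0[, 1L] + dx) + nx * (i0[, 2L] + dy) + nxy * (i0[, 3L] + dz) + 1
    d@dose[idx]
  }
  wx <- fr[, 1L]; wy <- fr[, 2L]; wz <- fr[, 3L]
  (1 - wz) * ((1 - wy) * ((1 - wx) * at(0, 0, 0) + wx * at(1, 0, 0)) +
              wy * ((1 - wx) * at(0, 1, 0) + wx * at(1, 1, 0))) +
    wz * ((1 - wy) * ((1 - wx) * at(0, 0, 1) + wx * at(1, 0, 1)) +
          wy * ((1 - wx) * at(0, 1, 1) + wx * at(1, 1, 1)))
}

## Dose sampled at the occupied voxel centers of m. On identical grids this
## is a direct lookup; otherwise trilinear interpolation at mask centers.
.doseAtMask <- function(d, m) {
  if (sum(m@occupancy) == 0L) stop("the structure mask is empty")
  if (sameGrid(d@grid, m@grid)) return(d@dose[m@occupancy])
  idx <- which(m@occupancy, arr.ind = TRUE) - 1L
  pts <- sweep(sweep(idx, 2L, m@grid@spacing, "*"), 2L, m@grid@origin, "+")
  .sampleDose(d, pts)
}

#' @rdname meanDose
#' @export
setGeneric("meanDose", function(d, m) standardGeneric("meanDose"))

#' Mean structure dose (D_mean)
#'
#' Mean of the dose sampled at every occupied voxel center of the structure.
#' When the structure and dose live on different grids the dose is sampled
#' by trilinear interpolation at the structure's voxel centers; on identical
#' grids this reduces exactly to a direct voxel lookup.
#'
#' @param d a \linkS4class{DoseGrid}
#' @param m a nonempty \linkS4class{StructureMask}
#' @return mean dose in Gy
#' @export
setMethod("meanDose", signature("DoseGrid", "StructureMask"),
          function(d, m) mean(.doseAtMask(d, m)))

#' @rdname coverageFraction
#' @export
setGeneric("coverageFraction",
           function(d, m, thresholdGy) standardGeneric("coverageFraction"))

#' Fraction of a structure at or above a dose threshold
#'
#' The V_d statistic: the fraction of the structure's occupied voxels whose
#' sampled dose is greater than or equal to \code{thresholdGy} (inclusive,
#' so a uniform dose exactly at threshold gives 1). Evaluated at the
#' structure's prescription dose this is the V100\% plan-coverage statistic.
#'
#' @param d a \linkS4class{DoseGrid}
#' @param m a nonempty \linkS4class{StructureMask}
#' @param thresholdGy dose threshold in Gy
#' @return fraction in [0, 1]
#' @export
setMethod("coverageFraction",
          signature("DoseGrid", "StructureMask", "numeric"),
          function(d, m, thresholdGy) {
  mean(.doseAtMask(d, m) >= thresholdGy)
})

#' Plan-inclusion filter on highest-PTV coverage
#'
#' Keeps plans whose highest-dose-PTV coverage V100\% is at least
#' \code{minCoverage} (inclusive: a plan at exactly the cutoff is kept,
#' since exclusion applies to coverage strictly below it). The companion
#' clause that compromised coverage must not overlap the GTV requires GTV
#' geometry this data model does not carry; it is recorded in the log as
#' not evaluated.
#'
#' @param plans list of \linkS4class{PlanMeta}
#' @param minCoverage inclusion cutoff, default 0.90
#' @return \code{list(included = <PlanMeta list>, exclusions = <data.frame
#'   with planId, v100, reason, gtvOverlapClause>)}
#' @export
filterPlans <- function(plans, minCoverage = 0.90) {
  stopifnot(all(vapply(plans, is, logical(1), "PlanMeta")))
  v <- vapply(plans, function(p) p@v100, numeric(1))
  if (anyNA(v)) {
    bad <- vapply(plans[is.na(v)], planId, character(1))
    stop("missing V100% coverage for plan(s): ", paste(bad, collapse = ", "))
  }
  keep <- if (length(plans)) v >= minCoverage else logical(0)
  nOut <- sum(!keep)
  excl <- data.frame(
    planId = vapply(plans[!keep], planId, character(1)),
    v100 = v[!keep],
    reason = sprintf("V100%% = %.4f < %.2f for the highest-dose PTV",
                     v[!keep], minCoverage),
    gtvOverlapClause = rep(
      "not evaluated (no GTV geometry in this data model)", nOut),
    stringsAsFactors = FALSE)
  list(included = plans[keep], exclusions = excl)
}
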