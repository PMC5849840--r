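#' @import methods
NULL

## ---------------------------------------------------------------------------
## Voxel-grid containers
## ---------------------------------------------------------------------------

#' VoxelGrid: a regular 3D lattice
#'
#' Describes the lattice on which structure masks and dose live: integer
#' dimensions, per-axis spacing in mm, and the physical position (mm) of the
#' center of voxel (0, 0, 0). Axis order is (x, y, z), with x the
#' fastest-varying index of the underlying arrays, matching R's column-major
#' layout. The center of voxel (i, j, k) (0-based) is
#' \code{origin + c(i, j, k) * spacing}.
#'
#' @slot dims integer(3), number of voxels per axis, all >= 1
#' @slot spacing numeric(3), mm per voxel along each axis, all > 0
#' @slot origin numeric(3), mm position of the first voxel center
#' @export
setClass("VoxelGrid",
  representation(dims = "integer", spacing = "numeric", origin = "numeric"))

setValidity("VoxelGrid", function(object) {
  msg <- character()
  if (length(object@dims) != 3L || any(is.na(object@dims)) ||
      any(object@dims < 1L))
    msg <- c(msg, "dims must be 3 integers, all >= 1")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 positive reals (mm)")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    msg <- c(msg, "origin must be 3 finite reals (mm)")
  if (length(msg)) msg else TRUE
})

#' Construct a VoxelGrid
#'
#' @param dims integer(3) voxel counts (nx, ny, nz)
#' @param spacing numeric(3) or scalar, mm per voxel
#' @param origin numeric(3), mm position of the center of voxel (0,0,0);
#'   default places the grid symmetrically about the physical origin
#' @return a \linkS4class{VoxelGrid}
#' @examples
#' VoxelGrid(c(64, 64, 32), spacing = 2)
#' @export
VoxelGrid <- function(dims, spacing = c(1, 1, 1), origin = NULL) {
  dims <- as.integer(dims)
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (is.null(origin)) origin <- -spacing * (dims - 1L) / 2
  new("VoxelGrid", dims = dims, spacing = spacing,
      origin = as.numeric(origin))
}

#' @describeIn VoxelGrid voxel counts per axis
#' @param x a VoxelGrid (or object carrying one)
#' @export
gridDims <- function(x) {
  if (is(x, "VoxelGrid")) x@dims else x@grid@dims
}

#' @describeIn VoxelGrid mm spacing per axis
#' @export
gridSpacing <- function(x) {
  if (is(x, "VoxelGrid")) x@spacing else x@grid@spacing
}

#' @describeIn VoxelGrid mm position of the first voxel center
#' @export
gridOrigin <- function(x) {
  if (is(x, "VoxelGrid")) x@origin else x@grid@origin
}

#' @describeIn VoxelGrid volume of one voxel in mm^3
#' @export
voxelVolumeMm3 <- function(x) prod(gridSpacing(x))

#' Voxel-center coordinates along one axis
#'
#' @param grid a \linkS4class{VoxelGrid}
#' @param axis 1 (x), 2 (y) or 3 (z)
#' @return numeric vector of mm positions of voxel centers
#' @export
axisCenters <- function(grid, axis) {
  grid@origin[axis] + (seq_len(grid@dims[axis]) - 1) * grid@spacing[axis]
}

sameGrid <- function(a, b, tol = 1e-9) {
  identical(a@dims, b@dims) &&
    all(abs(a@spacing - b@spacing) <= tol) &&
    all(abs(a@origin - b@origin) <= tol)
}

setMethod("show", "VoxelGrid", function(object) {
  cat("VoxelGrid:", paste(object@dims, collapse = " x "),
      "voxels, spacing", paste(format(object@spacing), collapse = "/"),
      "mm, origin (", paste(format(object@origin), collapse = ", "), ") mm\n")
})

#' StructureMask: boolean occupancy of a named structure
#'
#' @slot grid the \linkS4class{VoxelGrid} the mask lives on
#' @slot occupancy logical array with dim equal to the grid dims
#' @slot name structure label
#' @export
setClass("StructureMask",
  representation(grid = "VoxelGrid", occupancy = "array",
                 name = "character"))

setValidity("StructureMask", function(object) {
  msg <- character()
  if (!is.logical(object@occupancy))
    msg <- c(msg, "occupancy must be a logical array")
  if (!identical(dim(object@occupancy), object@grid@dims))
    msg <- c(msg, "occupancy shape must equal grid dims")
  if (anyNA(object@occupancy))
    msg <- c(msg, "occupancy must not contain NA")
  if (length(object@name) != 1L)
    msg <- c(msg, "name must be a single string")
  if (length(msg)) msg else TRUE
})

#' Construct a StructureMask
#'
#' @param grid a \linkS4class{VoxelGrid}
#' @param occupancy logical array (grid dims) or vector recycled to it
#' @param name structure label
#' @return a \linkS4class{StructureMask}
#' @export
StructureMask <- function(grid, occupancy, name = "structure") {
  occ <- array(as.logical(occupancy), dim = grid@dims)
  new("StructureMask", grid = grid, occupancy = occ, name = name)
}

#' @describeIn StructureMask the logical occupancy array
#' @param x a StructureMask
#' @export
occupancy <- function(x) x@occupancy

#' @describeIn StructureMask the structure label
#' @export
structureName <- function(x) x@name

setMethod("show", "StructureMask", function(object) {
  cat("StructureMask '", object@name, "': ",
      sum(object@occupancy), " / ", length(object@occupancy),
      " voxels occupied (", format(volumeCC(object), digits = 4),
      " cc)\n", sep = "")
})

#' DoseGrid: absorbed dose per voxel in Gy
#'
#' @slot grid the \linkS4class{VoxelGrid} the dose lives on
#' @slot dose numeric array (Gy), nonnegative, dim equal to grid dims
#' @export
setClass("DoseGrid",
  representation(grid = "VoxelGrid", dose = "array"))

setValidity("DoseGrid", function(object) {
  msg <- character()
  if (!is.numeric(object@dose))
    msg <- c(msg, "dose must be a numeric array")
  if (!identical(dim(object@dose), object@grid@dims))
    msg <- c(msg, "dose shape must equal grid dims")
  if (anyNA(object@dose) || any(object@dose < 0))
    msg <- c(msg, "dose must be nonnegative and free of NA")
  if (length(msg)) msg else TRUE
})

#' Construct a DoseGrid
#'
#' @param grid a \linkS4class{VoxelGrid}
#' @param dose numeric array (grid dims) or vector recycled to it, Gy
#' @return a \linkS4class{DoseGrid}
#' @export
DoseGrid <- function(grid, dose) {
  new("DoseGrid", grid = grid,
      dose = array(as.numeric(dose), dim = grid@dims))
}

#' @describeIn DoseGrid the numeric dose array (Gy)
#' @param x a DoseGrid
#' @export
doseArray <- function(x) x@dose

setMethod("show", "DoseGrid", function(object) {
  cat("DoseGrid:", paste(object@grid@dims, collapse = " x "),
      "voxels, dose range", format(min(object@dose), digits = 4), "-",
      format(max(object@dose), digits = 4), "Gy\n")
})

#' ContourSet: planar polygon contours of one structure
#'
#' Each contour is a planar polygon at a fixed z: a list with elements
#' \code{z} (mm) and \code{xy} (an n x 2 matrix of ordered vertices, mm,
#' implicitly closed). Multiple polygons on one slice combine by the even-odd
#' rule, so holes and islands are honored.
#'
#' @slot name structure label
#' @slot contours list of \code{list(z =, xy =)} polygons
#' @export
setClass("ContourSet",
  representation(name = "character", contours = "list"))

setValidity("ContourSet", function(object) {
  for (i in seq_along(object@contours)) {
    cn <- object@contours[[i]]
    if (!is.list(cn) || is.null(cn$z) || is.null(cn$xy))
      return(sprintf("contour %d must be list(z =, xy =)", i))
    if (!is.matrix(cn$xy) || ncol(cn$xy) != 2L || nrow(cn$xy) < 3L)
      return(sprintf("contour %d: polygon needs an n x 2 matrix, n >= 3", i))
  }
  TRUE
})

#' Construct a ContourSet
#'
#' @param name structure label
#' @param contours list of \code{list(z = <mm>, xy = <n x 2 matrix, mm>)}
#' @return a \linkS4class{ContourSet}
#' @export
ContourSet <- function(name, contours = list()) {
  new("ContourSet", name = name, contours = contours)
}

setMethod("show", "ContourSet", function(object) {
  cat("ContourSet '", object@name, "': ", length(object@contours),
      " polygon(s)\n", sep = "")
})

## ---------------------------------------------------------------------------
## Plan metadata and bundle
## ---------------------------------------------------------------------------

#' PlanMeta: per-plan prescription and acceptability metadata
#'
#' @slot planId plan identifier
#' @slot rxLevels numeric, 2-4 prescription doses in Gy, strictly descending
#' @slot v100 fraction of the highest-dose PTV covered by its prescription
#'   dose (plan-acceptability statistic), in [0, 1]; NA if unknown
#' @slot delivery free-text delivery metadata (recorded, never interpreted)
#' @export
setClass("PlanMeta",
  representation(planId = "character", rxLevels = "numeric",
                 v100 = "numeric", delivery = "character"))

setValidity("PlanMeta", function(object) {
  msg <- character()
  nl <- length(object@rxLevels)
  if (nl < 2L || nl > 4L)
    msg <- c(msg, "rxLevels must contain 2 to 4 dose levels")
  if (nl >= 2L && any(diff(object@rxLevels) >= 0))
    msg <- c(msg, "rxLevels must be strictly descending")
  if (length(object@v100) != 1L ||
      (!is.na(object@v100) && (object@v100 < 0 || object@v100 > 1)))
    msg <- c(msg, "v100 must be a single fraction in [0, 1] or NA")
  if (length(msg)) msg else TRUE
})

#' Construct a PlanMeta
#'
#' @param planId plan identifier
#' @param rxLevels prescription doses in Gy, strictly descending (2-4)
#' @param v100 highest-dose-PTV coverage fraction in [0, 1] (NA if unknown)
#' @param delivery free-text delivery metadata
#' @return a \linkS4class{PlanMeta}
#' @export
PlanMeta <- function(planId, rxLevels, v100 = NA_real_,
                     delivery = character()) {
  new("PlanMeta", planId = as.character(planId),
      rxLevels = as.numeric(rxLevels), v100 = as.numeric(v100),
      delivery = as.character(delivery))
}

#' @describeIn PlanMeta prescription levels in Gy (descending)
#' @param x a PlanMeta (or PlanBundle)
#' @export
rxLevels <- function(x) {
  if (is(x, "PlanBundle")) x@meta@rxLevels else x@rxLevels
}

#' @describeIn PlanMeta highest-dose-PTV coverage fraction
#' @export
planCoverage <- function(x) {
  if (is(x, "PlanBundle")) x@meta@v100 else x@v100
}

#' @describeIn PlanMeta plan identifier
#' @export
planId <- function(x) {
  if (is(x, "PlanBundle")) x@meta@planId else x@planId
}

setMethod("show", "PlanMeta", function(object) {
  cat("PlanMeta '", object@planId, "': Rx ",
      paste(object@rxLevels, collapse = "/"), " Gy, V100% = ",
      format(object@v100, digits = 4), "\n", sep = "")
})

#' PlanBundle: one plan's structures, dose and metadata
#'
#' @slot masks named list of \linkS4class{StructureMask}
#' @slot dose a \linkS4class{DoseGrid}, or NULL when no dosimetry is present
#' @slot meta a \linkS4class{PlanMeta}
#' @export
setClass("PlanBundle",
  representation(masks = "list", dose = "ANY", meta = "PlanMeta"))

setValidity("PlanBundle", function(object) {
  if (!all(vapply(object@masks, is, logical(1), "StructureMask")))
    return("masks must all be StructureMask objects")
  if (!is.null(object@dose) && !is(object@dose, "DoseGrid"))
    return("dose must be a DoseGrid or NULL")
  TRUE
})

#' Construct a PlanBundle
#'
#' @param masks list of \linkS4class{StructureMask} (named by structure)
#' @param dose a \linkS4class{DoseGrid} or NULL
#' @param meta a \linkS4class{PlanMeta}
#' @return a \linkS4class{PlanBundle}
#' @export
PlanBundle <- function(masks, dose = NULL, meta) {
  if (is.null(names(masks)) || any(names(masks) == ""))
    names(masks) <- vapply(masks, structureName, character(1))
  new("PlanBundle", masks = masks, dose = dose, meta = meta)
}

#' @describeIn PlanBundle the named list of structure masks
#' @param x a PlanBundle
#' @export
structureMasks <- function(x) x@masks

#' @describeIn PlanBundle the dose grid (NULL if absent)
#' @export
planDose <- function(x) x@dose

#' @describeIn PlanBundle the plan metadata
#' @export
planMeta <- function(x) x@meta

setMethod("show", "PlanBundle", function(object) {
  cat("PlanBundle '", object@meta@planId, "': ",
      length(object@masks), " structure(s) [",
      paste(names(object@masks), collapse = ", "), "], dose ",
      if (is.null(object@dose)) "absent" else "present", "\n", sep = "")
})

## ---------------------------------------------------------------------------
## Statistics containers
## ---------------------------------------------------------------------------

#' RegressionFit: an ordinary least squares fit summary
#'
#' @slot predictors predictor names (may be empty: intercept-only)
#' @slot coefficients named numeric, intercept first
#' @slot r2 coefficient of determination in [0, 1]
#' @slot pValue two-sided p-value of the slope t statistic (NA unless the
#'   model has exactly one predictor)
#' @slot slopeSE standard error of the slope (NA unless the model has
#'   exactly one predictor)
#' @slot aic Gaussian AIC with the error variance counted as a parameter
#' @slot n number of observations
#' @export
setClass("RegressionFit",
  representation(predictors = "character", coefficients = "numeric",
                 r2 = "numeric", pValue = "numeric", slopeSE = "numeric",
                 aic = "numeric", n = "integer"))

setValidity("RegressionFit", function(object) {
  msg <- character()
  if (object@r2 < -1e-12 || object@r2 > 1 + 1e-12)
    msg <- c(msg, "r2 must lie in [0, 1]")
  if (object@n <= length(object@coefficients))
    msg <- c(msg, "n must exceed the number of coefficients")
  if (length(msg)) msg else TRUE
})

setMethod("show", "RegressionFit", function(object) {
  cat("RegressionFit:",
      if (length(object@predictors)) paste(object@predictors, collapse = " + ")
      else "(intercept only)",
      sprintf("| n = %d, R^2 = %.4f, AIC = %.3f", object@n, object@r2,
              object@aic), "\n")
  print(round(object@coefficients, 6))
})

#' RocCurve: sensitivity/specificity sweep over score thresholds
#'
#' Candidate thresholds are -Inf, the midpoints between consecutive distinct
#' sorted scores, and +Inf; a case is called positive when its score is
#' strictly greater than the threshold. AUC is the trapezoidal area over
#' (1 - specificity, sensitivity).
#'
#' @slot thresholds ordered candidate thresholds (ascending)
#' @slot sensitivity per-threshold true positive fraction
#' @slot specificity per-threshold true negative fraction
#' @slot auc trapezoidal area under the curve
#' @export
setClass("RocCurve",
  representation(thresholds = "numeric", sensitivity = "numeric",
                 specificity = "numeric", auc = "numeric"))

setValidity("RocCurve", function(object) {
  msg <- character()
  k <- length(object@thresholds)
  if (length(object@sensitivity) != k || length(object@specificity) != k)
    msg <- c(msg, "thresholds, sensitivity, specificity must share a length")
  if (any(object@sensitivity < 0 | object@sensitivity > 1) ||
      any(object@specificity < 0 | object@specificity > 1))
    msg <- c(msg, "sensitivity and specificity must lie in [0, 1]")
  if (object@auc < 0 || object@auc > 1)
    msg <- c(msg, "auc must lie in [0, 1]")
  if (k >= 2 && (object@sensitivity[1] != 1 || object@specificity[1] != 0 ||
                 object@sensitivity[k] != 0 || object@specificity[k] != 1))
    msg <- c(msg, "curve must run from (sens 1, spec 0) to (sens 0, spec 1)")
  if (length(msg)) msg else TRUE
})

#' @describeIn RocCurve area under the ROC curve
#' @param x a RocCurve
#' @export
auc <- function(x) x@auc

setMethod("show", "RocCurve", function(object) {
  cat("RocCurve:", length(object@thresholds), "thresholds, AUC =",
      format(object@auc, digits = 4), "\n")
})

#' OperatingPoint: a chosen ROC threshold
#'
#' @slot threshold the score cutoff (positive iff score > threshold)
#' @slot sensitivity sensitivity at the cutoff
#' @slot specificity specificity at the cutoff
#' @slot youdenJ sensitivity + specificity - 1
#' @export
setClass("OperatingPoint",
  representation(threshold = "numeric", sensitivity = "numeric",
                 specificity = "numeric", youdenJ = "numeric"))

setValidity("OperatingPoint", function(object) {
  if (abs(object@youdenJ -
          (object@sensitivity + object@specificity - 1)) > 1e-9)
    return("youdenJ must equal sensitivity + specificity - 1")
  TRUE
})

setMethod("show", "OperatingPoint", function(object) {
  cat(sprintf(
    "OperatingPoint: threshold %.4g (sens %.3f, spec %.3f, J %.3f)\n",
    object@threshold, object@sensitivity, object@specificity,
    object@youdenJ))
})

#' PredictionRuleConfig: parameters of the tolerance-exceedance rule
#'
#' The shipped defaults are the clinically derived rule: a parotid that
#' overlaps the high-dose PTV plus a 5 mm expansion is predicted to exceed a
#' 26 Gy mean dose when that fractional overlap is greater than 0.083; a
#' parotid overlapping only the intermediate-dose PTV is predicted to exceed
#' when that overlap reaches 0.25; overlap with the low-dose PTV only (or no
#' overlap) predicts sparing.
#'
#' @slot toleranceGy parotid mean-dose tolerance (Gy), default 26
#' @slot hdMarginMm expansion margin of the high-dose PTV used by the
#'   scenario gate and the threshold statistic (mm), default 5
#' @slot thresholdHD05 positivity threshold on the high-dose-plus-margin
#'   fractional overlap, default 0.083 (strict >)
#' @slot thresholdIM positivity threshold on the intermediate-dose overlap,
#'   default 0.25 (inclusive >=)
#' @slot groupingMode "expansion" gates scenario A on the expanded high-dose
#'   PTV; "ptv" gates on the raw high-dose PTV
#' @export
setClass("PredictionRuleConfig",
  representation(toleranceGy = "numeric", hdMarginMm = "numeric",
                 thresholdHD05 = "numeric", thresholdIM = "numeric",
                 groupingMode = "character"))

setValidity("PredictionRuleConfig", function(object) {
  msg <- character()
  if (object@thresholdHD05 <= 0 || object@thresholdHD05 >= 1 ||
      object@thresholdIM <= 0 || object@thresholdIM >= 1)
    msg <- c(msg, "thresholds must lie in (0, 1)")
  if (object@hdMarginMm < 0)
    msg <- c(msg, "hdMarginMm must be >= 0")
  if (!object@groupingMode %in% c("expansion", "ptv"))
    msg <- c(msg, "groupingMode must be 'expansion' or 'ptv'")
  if (length(msg)) msg else TRUE
})

#' Construct a PredictionRuleConfig
#'
#' @param toleranceGy mean-dose tolerance in Gy
#' @param hdMarginMm high-dose PTV expansion margin in mm
#' @param thresholdHD05 threshold on OLV_HD05 (strict >)
#' @param thresholdIM threshold on OLV_IM (inclusive >=)
#' @param groupingMode "expansion" (default) or "ptv"
#' @return a \linkS4class{PredictionRuleConfig}
#' @export
PredictionRuleConfig <- function(toleranceGy = 26, hdMarginMm = 5,
                                 thresholdHD05 = 0.083, thresholdIM = 0.25,
                                 groupingMode = c("expansion", "ptv")) {
  new("PredictionRuleConfig", toleranceGy = toleranceGy,
      hdMarginMm = hdMarginMm, thresholdHD05 = thresholdHD05,
      thresholdIM = thresholdIM, groupingMode = match.arg(groupingMode))
}

setMethod("show", "PredictionRuleConfig", function(object) {
  cat(sprintf(
    paste0("PredictionRuleConfig: tolerance %.4g Gy | scenario A (%s, ",
           "margin %g mm): OLV > %.4g | scenario B: OLV >= %.4g\n"),
    object@toleranceGy, object@groupingMode, object@hdMarginMm,
    object@thresholdHD05, object@thresholdIM))
})
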