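#' Euclidean distance map of a structure
#'
#' Exact distance (mm), for every voxel center, to the nearest occupied voxel
#' center of \code{mask}, honoring per-axis spacing. Occupied voxels map to
#' 0; an empty mask maps everywhere to \code{Inf}. This is the primitive
#' behind millimetre-true isotropic expansion and the synthetic dose falloff.
#'
#' @param mask a \linkS4class{StructureMask}
#' @return numeric array (grid dims) of distances in mm
#' @export
distanceTransform <- function(mask) {
  stopifnot(is(mask, "StructureMask"))
  .edt3d(as.logical(mask@occupancy), mask@grid@dims, mask@grid@spacing)
}

#' @rdname expandMask
#' @export
setGeneric("expandMask", function(m, marginMm) standardGeneric("expandMask"))

#' Isotropic expansion of a structure by a physical margin
#'
#' A voxel of the result is occupied iff the Euclidean distance (mm, using
#' per-axis spacing) from its center to the nearest occupied input voxel
#' center is at most \code{marginMm}. The grid is unchanged, so expansions
#' clip at the array boundary; the margin is in true millimetres, making the
#' operation spacing-independent under anisotropic voxels.
#'
#' @param m a \linkS4class{StructureMask}
#' @param marginMm nonnegative expansion margin in mm
#' @return a \linkS4class{StructureMask} on the same grid
#' @examples
#' g <- VoxelGrid(c(9, 9, 9), spacing = 1)
#' seed <- StructureMask(g, array(FALSE, gridDims(g)))
#' occ <- occupancy(seed); occ[5, 5, 5] <- TRUE
#' sum(occupancy(expandMask(StructureMask(g, occ), 2)))  # 33 voxels
#' @export
setMethod("expandMask", "StructureMask", function(m, marginMm) {
  if (!is.numeric(marginMm) || length(marginMm) != 1L || is.na(marginMm) ||
      marginMm < 0)
    stop("marginMm must be a single nonnegative number")
  if (marginMm == 0) return(m)
  d <- distanceTransform(m)
  StructureMask(m@grid, d <= marginMm, name = m@name)
})

#' @rdname unionMasks
#' @export
setGeneric("unionMasks", function(masks) standardGeneric("unionMasks"))

#' Union of structure masks on a shared grid
#'
#' @param masks nonempty list of \linkS4class{StructureMask} on one grid
#' @return a \linkS4class{StructureMask}; the name joins the inputs' names
#' @export
setMethod("unionMasks", "list", function(masks) {
  if (length(masks) == 0L) stop("unionMasks needs at least one mask")
  stopifnot(all(vapply(masks, is, logical(1), "StructureMask")))
  g <- masks[[1L]]@grid
  for (m in masks[-1L]) {
    if (!sameGrid(g, m@grid))
      stop("unionMasks: masks must share one grid")
  }
  occ <- Reduce(`|`, lapply(masks, occupancy))
  StructureMask(g, occ,
                name = paste(vapply(masks, structureName, character(1)),
                             collapse = "+"))
})

#' @rdname volumeCC
#' @export
setGeneric("volumeCC", function(m) standardGeneric("volumeCC"))

#' Structure volume in cubic centimetres
#'
#' Occupied-voxel count times voxel volume (mm^3), divided by 1000.
#'
#' @param m a \linkS4class{StructureMask}
#' @return volume in cc
#' @export
setMethod("volumeCC", "StructureMask", function(m) {
  sum(m@occupancy) * voxelVolumeMm3(m@grid) / 1000
})

#' @rdname fractionalOverlap
#' @export
setGeneric("fractionalOverlap",
           function(parotid, target) standardGeneric("fractionalOverlap"))

#' Fractional overlap of an organ with a target
#'
#' The ratio of the overlapping volume between the organ (here, a parotid
#' gland) and the target to the organ's own volume, by voxel count on the
#' shared grid. This purely geometric statistic is the predictor the
#' tolerance rule is built on.
#'
#' @param parotid a nonempty \linkS4class{StructureMask}
#' @param target a \linkS4class{StructureMask} on the same grid
#' @return a fraction in [0, 1]
#' @export
setMethod("fractionalOverlap", signature("StructureMask", "StructureMask"),
          function(parotid, target) {
  if (!sameGrid(parotid@grid, target@grid))
    stop("fractionalOverlap: masks must share one grid")
  np <- sum(parotid@occupancy)
  if (np == 0L)
    stop("fractionalOverlap: the parotid mask is empty (undefined ratio)")
  sum(parotid@occupancy & target@occupancy) / np
})
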