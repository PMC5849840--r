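## Contour rasterization and plan-bundle I/O.
##
## A plan bundle on disk is one directory per plan: each structure mask and
## the dose stored as a single-volume ascii NRRD (x fastest, matching R's
## column-major order; "spacings" and "axis mins" carry the mm geometry),
## plus a meta.json sidecar with the prescription levels and V100%.

## even-odd point-in-polygon test, vectorized over query points
.pointsInPolygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    yi <- vy[i]; yj <- vy[j]
    if (yi != yj) {
      cross <- ((yi > py) != (yj > py)) &
        (px < (vx[j] - vx[i]) * (py - yi) / (yj - yi) + vx[i])
      inside <- xor(inside, cross)
    }
    j <- i
  }
  inside
}

#' Rasterize planar contours onto a voxel grid
#'
#' A voxel is occupied iff its center lies inside an odd number of that
#' slice's polygons (even-odd rule; multiple polygons on one slice combine
#' by XOR, so holes and islands are honored). Each contour's z must lie
#' within half a slice spacing of some grid slice and snaps to it.
#'
#' @param cs a \linkS4class{ContourSet}
#' @param grid the target \linkS4class{VoxelGrid}
#' @return a \linkS4class{StructureMask}
#' @export
rasterizeContours <- function(cs, grid) {
  stopifnot(is(cs, "ContourSet"), is(grid, "VoxelGrid"))
  occ <- array(FALSE, dim = grid@dims)
  sz <- grid@spacing[3L]
  xs <- axisCenters(grid, 1L)
  ys <- axisCenters(grid, 2L)
  px <- rep(xs, times = grid@dims[2L])
  py <- rep(ys, each = grid@dims[1L])
  for (i in seq_along(cs@contours)) {
    cn <- cs@contours[[i]]
    if (nrow(cn$xy) < 3L)
      stop(sprintf("contour %d of '%s' is degenerate (< 3 vertices)",
                   i, cs@name))
    k <- round((cn$z - grid@origin[3L]) / sz)
    zk <- grid@origin[3L] + k * sz
    if (k < 0 || k >= grid@dims[3L] || abs(cn$z - zk) > sz / 2 + 1e-9)
      stop(sprintf(
        "contour %d of '%s' (z = %g mm) lies farther than sz/2 from any slice",
        i, cs@name, cn$z))
    inside <- .pointsInPolygon(px, py, cn$xy[, 1L], cn$xy[, 2L])
    occ[, , k + 1L] <- xor(occ[, , k + 1L],
                           matrix(inside, grid@dims[1L], grid@dims[2L]))
  }
  StructureMask(grid, occ, name = cs@name)
}

## ---------------------------------------------------------------------------
## Minimal ascii NRRD reader/writer (text-only on disk)
## ---------------------------------------------------------------------------

.writeNrrd <- function(path, values, dims, spacing, origin, type) {
  con <- file(path, "wb")  # "wb" for deterministic \n line endings
  on.exit(close(con))
  hdr <- c(
    "NRRD0004",
    paste0("type: ", type),
    "dimension: 3",
    paste0("sizes: ", paste(dims, collapse = " ")),
    paste0("spacings: ", paste(sprintf("%.17g", spacing), collapse = " ")),
    paste0("axis mins: ", paste(sprintf("%.17g", origin), collapse = " ")),
    "encoding: ascii",
    "")
  writeLines(hdr, con, sep = "\n")
  txt <- if (type == "uchar") as.character(as.integer(values))
         else sprintf("%.17g", values)
  nper <- 16L
  idx <- seq(1L, length(txt), by = nper)
  lines <- vapply(idx, function(i)
    paste(txt[i:min(i + nper - 1L, length(txt))], collapse = " "),
    character(1))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

.readNrrd <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1L], "NRRD"))
    stop("not an NRRD file: ", path)
  blank <- which(lines == "")[1L]
  if (is.na(blank)) stop("NRRD header not terminated by a blank line: ", path)
  hdr <- lines[2:(blank - 1L)]
  hdr <- hdr[!startsWith(hdr, "#")]
  fields <- list()
  for (h in hdr) {
    kv <- regmatches(h, regexec("^([^:]+):[ ]?(.*)$", h))[[1L]]
    if (length(kv) == 3L) fields[[kv[2L]]] <- kv[3L]
  }
  need <- c("type", "sizes", "spacings", "axis mins", "encoding")
  miss <- setdiff(need, names(fields))
  if (length(miss))
    stop("NRRD header missing field(s): ", paste(miss, collapse = ", "))
  if (fields[["encoding"]] != "ascii")
    stop("only ascii NRRD encoding is supported")
  dims <- as.integer(strsplit(trimws(fields[["sizes"]]), "[ ]+")[[1L]])
  spacing <- as.numeric(strsplit(trimws(fields[["spacings"]]), "[ ]+")[[1L]])
  origin <- as.numeric(strsplit(trimws(fields[["axis mins"]]), "[ ]+")[[1L]])
  vals <- scan(text = lines[(blank + 1L):length(lines)], what = double(),
               quiet = TRUE)
  if (length(vals) != prod(dims))
    stop(sprintf("NRRD data length %d disagrees with declared sizes %s in %s",
                 length(vals), paste(dims, collapse = "x"), path))
  list(values = vals, dims = dims, spacing = spacing, origin = origin,
       type = fields[["type"]])
}

## ---------------------------------------------------------------------------
## Plan bundles
## ---------------------------------------------------------------------------

#' Write a plan bundle to a directory
#'
#' Emits one ascii NRRD per structure mask, \code{dose.nrrd} when dose is
#' present, and a \code{meta.json} sidecar. \code{loadPlanBundle} of the
#' result reproduces the bundle's content exactly.
#'
#' @param bundle a \linkS4class{PlanBundle}
#' @param dir output directory (created if needed)
#' @return \code{dir}, invisibly
#' @export
writePlanBundle <- function(bundle, dir) {
  stopifnot(is(bundle, "PlanBundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  safe <- function(nm) gsub("[^A-Za-z0-9_.-]", "_", nm)
  files <- character(0)
  for (nm in names(bundle@masks)) {
    m <- bundle@masks[[nm]]
    f <- paste0(safe(nm), ".nrrd")
    .writeNrrd(file.path(dir, f), m@occupancy, m@grid@dims,
               m@grid@spacing, m@grid@origin, type = "uchar")
    files[nm] <- f
  }
  if (!is.null(bundle@dose)) {
    d <- bundle@dose
    .writeNrrd(file.path(dir, "dose.nrrd"), d@dose, d@grid@dims,
               d@grid@spacing, d@grid@origin, type = "double")
  }
  meta <- list(plan_id = bundle@meta@planId,
               rx_levels = bundle@meta@rxLevels,
               v100 = bundle@meta@v100,
               delivery = bundle@meta@delivery,
               structures = as.list(files),
               dose = !is.null(bundle@dose))
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  invisible(dir)
}

#' Load a plan bundle from a directory
#'
#' @param dir bundle directory written by \code{\link{writePlanBundle}}
#' @param needDose error when TRUE and the bundle carries no dose; when
#'   FALSE a dose-less bundle loads with \code{planDose(x)} NULL
#' @return a \linkS4class{PlanBundle}
#' @export
loadPlanBundle <- function(dir, needDose = FALSE) {
  mf <- file.path(dir, "meta.json")
  if (!file.exists(mf)) stop("no meta.json in ", dir)
  meta <- jsonlite::read_json(mf, simplifyVector = TRUE)
  masks <- list()
  for (nm in names(meta$structures)) {
    nr <- .readNrrd(file.path(dir, meta$structures[[nm]]))
    g <- VoxelGrid(nr$dims, nr$spacing, nr$origin)
    masks[[nm]] <- StructureMask(g, array(nr$values != 0, dim = nr$dims),
                                 name = nm)
  }
  dose <- NULL
  df <- file.path(dir, "dose.nrrd")
  if (isTRUE(meta$dose) && file.exists(df)) {
    nr <- .readNrrd(df)
    g <- VoxelGrid(nr$dims, nr$spacing, nr$origin)
    dose <- DoseGrid(g, array(nr$values, dim = nr$dims))
  } else if (needDose) {
    stop("bundle in ", dir, " carries no dose, but dosimetry was requested")
  }
  pm <- PlanMeta(meta$plan_id, unlist(meta$rx_levels),
                 v100 = if (is.null(meta$v100)) NA_real_ else meta$v100,
                 delivery = unlist(meta$delivery) %||% character())
  PlanBundle(masks, dose = dose, meta = pm)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
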