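# Independent oracles and small fixture builders.

# brute-force mm-true dilation: voxel occupied iff some occupied source
# voxel center lies within marginMm (straight double loop over coordinates)
bruteExpand <- function(occ, spacing, marginMm) {
  dims <- dim(occ)
  src <- which(occ, arr.ind = TRUE)
  if (nrow(src) == 0L) return(occ & FALSE)
  all <- as.matrix(expand.grid(i = seq_len(dims[1]), j = seq_len(dims[2]),
                               k = seq_len(dims[3])))
  srcMm <- sweep(src, 2L, spacing, "*")
  allMm <- sweep(all, 2L, spacing, "*")
  out <- logical(nrow(all))
  for (r in seq_len(nrow(src))) {
    d2 <- (allMm[, 1] - srcMm[r, 1])^2 + (allMm[, 2] - srcMm[r, 2])^2 +
      (allMm[, 3] - srcMm[r, 3])^2
    out <- out | (d2 <= marginMm^2)
  }
  array(out, dims)
}

# Mann-Whitney pair-count AUC with ties counted one half
pairCountAUC <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# exhaustive best-AIC subset of named predictor columns
exhaustiveAIC <- function(y, X) {
  nms <- colnames(X)
  best <- NULL
  bestAic <- Inf
  for (sz in 0:length(nms)) {
    for (sub in if (sz == 0) list(character(0)) else
         asplit(utils::combn(nms, sz), 2L)) {
      a <- fitLinear(y, X[, unlist(sub), drop = FALSE])@aic
      if (a < bestAic) { bestAic <- a; best <- unlist(sub) }
    }
  }
  list(selected = best, aic = bestAic)
}

# single-voxel-at-center mask on a small isotropic grid
pointMask <- function(n = 9L, spacing = c(1, 1, 1), at = NULL) {
  g <- VoxelGrid(rep(n, 3L), spacing)
  occ <- array(FALSE, gridDims(g))
  if (is.null(at)) at <- rep((n + 1L) %/% 2L, 3L)
  occ[at[1], at[2], at[3]] <- TRUE
  StructureMask(g, occ)
}

randomMask <- function(dims, spacing, p = 0.08) {
  g <- VoxelGrid(dims, spacing)
  StructureMask(g, array(runif(prod(dims)) < p, dims))
}

# a one-row parotid record with given overlap statistics
recordRow <- function(OLV_HD = 0, OLV_HD05 = 0, OLV_IM = NA_real_,
                      OLV_LD = 0, OLV_CT = OLV_LD, Dmean = NA_real_) {
  data.frame(planId = "fixture", side = "left", parotidVolumeCC = 30,
             OLV_CT = OLV_CT, OLV_CT05 = OLV_CT, OLV_CT10 = OLV_CT,
             OLV_HD = OLV_HD, OLV_HD05 = OLV_HD05, OLV_IM = OLV_IM,
             OLV_LD = OLV_LD, Dmean = Dmean,
             positive = if (is.na(Dmean)) NA else Dmean > 26,
             stringsAsFactors = FALSE)
}
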