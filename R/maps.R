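## Back-projection of feature-space vectors into 3D maps, thresholding, and
## connected-component cluster tables with world-coordinate peaks.

#' Back-project a feature vector into a 3D map
#'
#' Inverse of the feature-table flattening: the vector's entries are placed
#' at their in-mask voxel coordinates; out-of-mask voxels are zero.
#'
#' @param v Numeric vector, one entry per in-mask voxel.
#' @param coords V x 3 matrix of 1-based voxel coordinates (the feature
#'   table's index map order).
#' @param dm Grid dimension (length 3).
#' @return 3D numeric array.
#' @export
vectorToMap <- function(v, coords, dm) {
  if (length(v) != nrow(coords))
    stop("vector length (", length(v), ") != in-mask voxel count (",
         nrow(coords), ")")
  vecToVolume(v, coords, dm)
}

#' Retain the top percent of a map by absolute value
#'
#' Keeps the `ceiling(pct/100 * V)` in-mask voxels of largest absolute value
#' (signs preserved) and zeroes the rest. Ties at the cutoff are all
#' retained; if that enlarges the kept set a message reports it.
#'
#' @param map 3D numeric array.
#' @param mask Logical array of in-mask voxels.
#' @param pct Percentage in (0, 100].
#' @return Thresholded map.
#' @export
topPercentThreshold <- function(map, mask, pct = 1) {
  stopifnot(pct > 0, pct <= 100)
  idx <- which(as.logical(mask))
  if (length(idx) == 0L) stop("empty mask")
  a <- abs(map[idx])
  nKeep <- ceiling(pct / 100 * length(idx))
  cutoff <- sort(a, decreasing = TRUE)[nKeep]
  keepIdx <- idx[a >= cutoff]
  if (length(keepIdx) > nKeep)
    message("ties at the cutoff: retaining ", length(keepIdx),
            " voxels instead of ", nKeep)
  out <- array(0, dim(map))
  out[keepIdx] <- map[keepIdx]
  out
}

#' Extract suprathreshold clusters from a thresholded map
#'
#' Labels connected components of the nonzero voxels (zeros are background).
#' By default positive and negative voxels are labeled separately so
#' opposite-signed clusters never merge through adjacency. Components smaller
#' than `minSize` are dropped; records are sorted by size, descending.
#'
#' @param map 3D array, already thresholded.
#' @param minSize Minimum cluster extent in voxels.
#' @param connectivity 6, 18 or 26 (default).
#' @param affine Optional 4x4 voxel-to-world affine for peak coordinates
#'   (0-based index convention); without it peak voxel indices are reported.
#' @param signSplit Label positive and negative voxels separately.
#' @return Data.frame with one row per cluster: `size`, `peakValue`, `sign`,
#'   `peakX`, `peakY`, `peakZ` (world mm if `affine` given, else 1-based
#'   voxel indices), plus a list column `voxels` of V x 3 coordinate
#'   matrices.
#' @export
extractClusters <- function(map, minSize = 100L, connectivity = 26L,
                            affine = NULL, signSplit = TRUE) {
  dm <- dim(map)
  groups <- if (signSplit) list(which(map > 0), which(map < 0))
            else list(which(map != 0))
  rows <- list()
  for (g in groups) {
    if (length(g) == 0L) next
    lab <- labelComponents3d(g, dm, connectivity)
    for (cl in unique(lab)) {
      lin <- g[lab == cl]
      if (length(lin) < minSize) next
      vals <- map[lin]
      pk <- lin[which.max(abs(vals))]
      pkCoord <- as.integer(arrayInd(pk, dm))
      world <- if (is.null(affine)) pkCoord else peakToWorld(pkCoord, affine)
      rows[[length(rows) + 1L]] <- data.frame(
        size = length(lin), peakValue = map[pk],
        sign = if (map[pk] > 0) 1L else -1L,
        peakX = world[1], peakY = world[2], peakZ = world[3])
      rows[[length(rows)]]$voxels <- I(list(arrayInd(lin, dm)))
    }
  }
  if (length(rows) == 0L)
    return(data.frame(size = integer(0), peakValue = numeric(0),
                      sign = integer(0), peakX = numeric(0),
                      peakY = numeric(0), peakZ = numeric(0)))
  out <- do.call(rbind, rows)
  out <- out[order(-out$size), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Voxel index to world (mm) coordinates
#'
#' Applies the NIfTI affine, which maps 0-based voxel indices to mm; R-side
#' 1-based indices are converted internally.
#'
#' @param ijk Voxel index triple (1-based by default).
#' @param affine 4x4 voxel-to-world matrix (must be invertible).
#' @param oneBased Is `ijk` 1-based (R convention)?
#' @return Numeric length-3 world coordinate in mm.
#' @export
peakToWorld <- function(ijk, affine, oneBased = TRUE) {
  if (abs(det(affine)) < 1e-12) stop("singular affine")
  idx0 <- as.numeric(ijk) - if (oneBased) 1 else 0
  as.numeric(affine %*% c(idx0, 1))[1:3]
}

#' World (mm) to voxel index coordinates
#'
#' @param xyz World coordinate in mm.
#' @param affine 4x4 voxel-to-world matrix.
#' @param oneBased Return 1-based indices (R convention)?
#' @return Numeric length-3 voxel index.
#' @export
worldToVoxel <- function(xyz, affine, oneBased = TRUE) {
  if (abs(det(affine)) < 1e-12) stop("singular affine")
  as.numeric(solve(affine) %*% c(as.numeric(xyz), 1))[1:3] +
    if (oneBased) 1 else 0
}
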