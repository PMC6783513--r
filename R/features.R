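## Per-subject connectivity features: voxel-wise FCS, large-scale FC, ReHo.

#' Feature extraction settings
#'
#' @param kind `"fcs"` (voxel-wise functional connectivity strength),
#'   `"lsfc"` (large-scale node-pair FC) or `"reho"` (regional homogeneity).
#' @param rThreshold Correlation threshold for FCS; correlations at or below
#'   it (including all negative ones) are excluded from the sum. Strictly
#'   greater-than, in (0, 1).
#' @param neighborhood ReHo cluster size including the center voxel: 7, 19
#'   or 27.
#' @param smoothFwhmMm Gaussian smoothing FWHM in mm (0 disables).
#' @param gmProbThreshold Gray-matter probability threshold (strict `>`).
#' @param fcsScaling How the FCS map is converted to z values: `"map"`
#'   standardizes the map within the mask; `"fisher"` instead applies
#'   arctanh to each suprathreshold correlation before summation.
#' @param renormalizeSmoothing Divide by the smoothed mask to remove edge
#'   attenuation (recommended for small synthetic masks).
#' @return A validated list of class `FeatureSpec`.
#' @export
featureSpec <- function(kind = c("fcs", "lsfc", "reho"), rThreshold = 0.25,
                        neighborhood = 27L, smoothFwhmMm = 6,
                        gmProbThreshold = 0.2,
                        fcsScaling = c("map", "fisher"),
                        renormalizeSmoothing = TRUE) {
  kind <- match.arg(kind)
  fcsScaling <- match.arg(fcsScaling)
  stopifnot(rThreshold > 0, rThreshold < 1,
            neighborhood %in% c(7L, 19L, 27L), smoothFwhmMm >= 0)
  structure(list(kind = kind, rThreshold = rThreshold,
                 neighborhood = as.integer(neighborhood),
                 smoothFwhmMm = smoothFwhmMm,
                 gmProbThreshold = gmProbThreshold,
                 fcsScaling = fcsScaling,
                 renormalizeSmoothing = renormalizeSmoothing),
            class = "FeatureSpec")
}

#' Binary gray-matter mask from a probability map
#'
#' A voxel is included iff its probability is strictly greater than the
#' threshold.
#'
#' @param prob 3D array of probabilities in [0, 1].
#' @param threshold Probability threshold (default 0.2).
#' @return Logical array of the same dimension.
#' @export
makeGMMask <- function(prob, threshold = 0.2) {
  if (min(prob) < 0 || max(prob) > 1)
    stop("probability map values must lie in [0, 1]")
  prob > threshold
}

#' Voxel-wise functional connectivity strength
#'
#' For each in-mask voxel, the sum of its Pearson correlations with all other
#' in-mask voxels that exceed `rThreshold` (weak and negative correlations
#' removed; the self-correlation is excluded). Computed in column chunks so
#' the full voxel-by-voxel correlation matrix is never materialized at once.
#'
#' @param x Timepoints x voxels matrix of in-mask series, or a
#'   [BOLDSeries-class] plus logical `mask` array.
#' @param rThreshold Correlation threshold (strict `>`).
#' @param chunkSize Number of voxels correlated per block.
#' @param mask Logical 3D array (BOLDSeries method only).
#' @return Numeric FCS per in-mask voxel (matrix method) or a 3D map with
#'   zeros outside the mask (BOLDSeries method).
#' @export
setGeneric("voxelwiseFCS", function(x, rThreshold = 0.25, chunkSize = 512L,
                                    mask = NULL)
  standardGeneric("voxelwiseFCS"))

#' @rdname voxelwiseFCS
#' @export
setMethod("voxelwiseFCS", "matrix",
  function(x, rThreshold = 0.25, chunkSize = 512L, mask = NULL) {
    fcsCore(x, rThreshold, chunkSize)
  })

#' @rdname voxelwiseFCS
#' @export
setMethod("voxelwiseFCS", "BOLDSeries",
  function(x, rThreshold = 0.25, chunkSize = 512L, mask = NULL) {
    stopifnot(!is.null(mask))
    d <- dim(x@data)
    lin <- which(as.logical(mask))
    m <- t(matrix(x@data, prod(d[1:3]), d[4])[lin, , drop = FALSE])
    v <- fcsCore(m, rThreshold, chunkSize)
    out <- array(0, d[1:3])
    out[lin] <- v
    out
  })

fcsCore <- function(x, rThreshold, chunkSize = 512L, fisher = FALSE) {
  nV <- ncol(x)
  if (nV < 2L) stop("FCS needs at least 2 in-mask voxels")
  sds <- apply(x, 2L, sd)
  if (any(sds < 1e-12))
    stop("zero-variance series at voxel index: ",
         paste(head(which(sds < 1e-12), 10L), collapse = ", "))
  xs <- scale(x)  # sample sd
  n1 <- nrow(x) - 1L
  fcs <- numeric(nV)
  starts <- seq.int(1L, nV, by = chunkSize)
  for (s in starts) {
    cols <- s:min(s + chunkSize - 1L, nV)
    r <- crossprod(xs, xs[, cols, drop = FALSE]) / n1
    r[cbind(cols, seq_along(cols))] <- 0  # exclude self-correlation
    keep <- r > rThreshold
    fcs[cols] <- if (fisher) colSums(atanh(pmin(r, 1 - 1e-7)) * keep)
                 else colSums(r * keep)
  }
  fcs
}

#' Standardize a map within a mask
#'
#' Subtracts the in-mask mean and divides by the in-mask population standard
#' deviation; out-of-mask values are untouched (vector input standardizes
#' everything).
#'
#' @param map Numeric vector or 3D array.
#' @param mask Logical selection of the in-mask entries (default all).
#' @return Standardized map (in-mask mean 0, population sd 1).
#' @export
zscoreMap <- function(map, mask = NULL) {
  idx <- if (is.null(mask)) seq_along(map) else which(as.logical(mask))
  v <- map[idx]
  s <- sqrt(mean((v - mean(v))^2))
  if (s < 1e-12) stop("constant map: in-mask standard deviation is zero")
  map[idx] <- (v - mean(v)) / s
  map
}

#' Fisher r-to-z transformation
#'
#' `atanh(r)`, with `|r| >= 1` clamped to `1 - 1e-7` in absolute value (with
#' a warning) so duplicated series cannot produce infinities.
#'
#' @param r Correlations.
#' @return `atanh` of the (possibly clamped) input.
#' @export
fisherZ <- function(r) {
  if (any(abs(r) >= 1)) {
    warning("correlations with |r| >= 1 clamped before Fisher transform")
    r <- pmin(pmax(r, -1 + 1e-7), 1 - 1e-7)
  }
  atanh(r)
}

#' Gaussian spatial smoothing
#'
#' Separable Gaussian smoothing with kernel sigma
#' `fwhm / (sqrt(8 log 2) * voxelSize)` voxels per axis. With a mask the map
#' is zero-filled, smoothed on the full grid, then re-masked; with
#' `renormalize = TRUE` it is divided by the smoothed mask so a constant
#' in-mask image stays constant (no edge attenuation).
#'
#' @param map 3D numeric array.
#' @param fwhmMm FWHM in mm (scalar or per-axis length 3; 0 = identity).
#' @param voxelSizeMm Voxel size in mm.
#' @param mask Optional logical array.
#' @param renormalize Divide by the smoothed mask (mask input only).
#' @return Smoothed array.
#' @export
gaussianSmooth <- function(map, fwhmMm, voxelSizeMm, mask = NULL,
                           renormalize = TRUE) {
  if (any(fwhmMm < 0)) stop("fwhm must be non-negative")
  if (all(fwhmMm == 0)) {
    if (!is.null(mask)) map[!mask] <- 0
    return(map)
  }
  Ks <- axisKernels(dim(map), fwhmMm, voxelSizeMm)
  if (is.null(mask)) return(smoothWithKernels(map, Ks))
  mask <- as.logical(mask); dim(mask) <- dim(map)
  z <- map; z[!mask] <- 0
  s <- smoothWithKernels(z, Ks)
  if (renormalize) {
    w <- smoothWithKernels(array(as.numeric(mask), dim(map)), Ks)
    ok <- mask & w > 1e-12
    s[ok] <- s[ok] / w[ok]
  }
  s[!mask] <- 0
  s
}

#' Kendall's coefficient of concordance over time
#'
#' Ranks each series over time (midranks for ties) and evaluates
#' `W = 12 sum_t (R_t - Rbar)^2 / (K^2 (n^3 - n))` where `R_t` is the rank
#' sum at timepoint `t`. No tie-correction term is applied. Constant series
#' (all-tied ranks) are allowed but flagged with a warning.
#'
#' @param block Numeric matrix with timepoints in rows and the K series in
#'   columns (K >= 2, n >= 2).
#' @return W in [0, 1].
#' @export
kendallsW <- function(block) {
  block <- as.matrix(block)
  n <- nrow(block); K <- ncol(block)
  if (K < 2L || n < 2L) stop("need at least 2 series and 2 timepoints")
  if (any(apply(block, 2L, function(col) diff(range(col)) == 0)))
    warning("constant series: W computed with midranks")
  R <- rowSums(columnRanks(block))
  12 * sum((R - mean(R))^2) / (K^2 * (n^3 - n))
}

## ReHo over all in-mask voxels at once: the rank matrix is multiplied by the
## sparse voxel-to-neighborhood incidence, giving every voxel's rank sum per
## timepoint in two passes.
rehoCore <- function(x, coords, dm, neighborhood = 27L) {
  nV <- ncol(x); n <- nrow(x)
  offs <- rbind(c(0L, 0L, 0L),
                connectivityOffsets(c(`7` = 6, `19` = 18, `27` = 26)[
                  as.character(neighborhood)]))
  memb <- integer(prod(dm))
  lin <- coordsToLinear(coords, dm)
  memb[lin] <- seq_len(nV)
  ii <- integer(0); jj <- integer(0)
  for (o in seq_len(nrow(offs))) {
    nb <- sweep(coords, 2L, -offs[o, ])
    ok <- nb[, 1] >= 1L & nb[, 1] <= dm[1] & nb[, 2] >= 1L &
      nb[, 2] <= dm[2] & nb[, 3] >= 1L & nb[, 3] <= dm[3]
    hit <- integer(nV)
    hit[ok] <- memb[coordsToLinear(nb[ok, , drop = FALSE], dm)]
    found <- which(hit > 0L)
    ii <- c(ii, found)
    jj <- c(jj, hit[found])
  }
  A <- Matrix::sparseMatrix(i = jj, j = ii, x = 1, dims = c(nV, nV))
  K <- Matrix::colSums(A)
  ranks <- columnRanks(x)
  S <- as.matrix(ranks %*% A)      # rank sums per timepoint and voxel
  ss <- colSums(S^2) - n * (K * (n + 1) / 2)^2
  W <- 12 * ss / (K^2 * (n^3 - n))
  if (any(K == 1L)) {
    warning(sum(K == 1L), " voxel(s) with no in-mask neighbors set to 0")
    W[K == 1L] <- 0
  }
  attr(W, "K") <- as.integer(K)
  W
}

#' Regional homogeneity map
#'
#' Kendall's W of each voxel's series with its in-mask spatial neighbors
#' (26-, 18- or 6-neighborhood; edge voxels use the neighbors available).
#'
#' @param x Timepoints x in-mask-voxels matrix.
#' @param coords V x 3 matrix of the in-mask voxel coordinates.
#' @param dm Grid dimension (length 3).
#' @param neighborhood Cluster size including the center: 7, 19 or 27.
#' @return Numeric W per in-mask voxel, with attribute `K` (neighbors used).
#' @export
rehoMap <- function(x, coords, dm, neighborhood = 27L) {
  stopifnot(neighborhood %in% c(7L, 19L, 27L), ncol(x) == nrow(coords))
  rehoCore(x, coords, dm, neighborhood)
}

#' Normalize a ReHo map by its in-mask mean
#'
#' @param w Numeric vector of in-mask ReHo values.
#' @return `w / mean(w)`; the normalized values average exactly 1.
#' @export
normalizeReho <- function(w) {
  m <- mean(w)
  if (m <= 0) stop("cannot normalize: non-positive mean ReHo")
  w / m
}

#' Node-mean time series
#'
#' Averages the series of all voxels sharing each parcel label.
#'
#' @param x Timepoints x voxels matrix.
#' @param labels Integer parcel label per voxel (1..N).
#' @param dropEmpty Drop empty labels instead of erroring.
#' @return Nodes x timepoints matrix; rownames are the node labels.
#' @export
nodeTimeseries <- function(x, labels, dropEmpty = FALSE) {
  labels <- as.integer(labels)
  N <- max(labels)
  present <- sort(unique(labels))
  missing <- setdiff(seq_len(N), present)
  if (length(missing) > 0L && !dropEmpty)
    stop("empty node label(s): ", paste(missing, collapse = ", "))
  sums <- rowsum(t(x), labels)             # nodes x timepoints
  counts <- as.numeric(table(labels)[rownames(sums)])
  sums / counts
}

#' Large-scale FC vector from node time series
#'
#' Pearson correlation of every unordered node pair, Fisher z-transformed,
#' packed in row-major strict upper-triangle order: (1,2), (1,3), ...,
#' (1,N), (2,3), ... The pair index map is attached as attribute `map`.
#'
#' @param nodeTs Nodes x timepoints matrix (all rows non-constant).
#' @return Numeric vector of length `N (N - 1) / 2` with attribute `map`
#'   (data.frame `node1`, `node2`).
#' @export
largescaleFC <- function(nodeTs) {
  N <- nrow(nodeTs)
  if (N < 2L) stop("need at least 2 nodes")
  if (any(apply(nodeTs, 1L, function(r) diff(range(r)) == 0)))
    stop("constant node time series")
  r <- cor(t(nodeTs))
  i <- rep(seq_len(N - 1L), times = (N - 1L):1L)
  j <- sequence((N - 1L):1L) + i
  v <- fisherZ(r[cbind(i, j)])
  attr(v, "map") <- data.frame(node1 = i, node2 = j)
  v
}

#' Build the subjects x features table for a cohort
#'
#' Runs the requested feature extraction for every subject of a preprocessed
#' cohort and assembles a [FeatureTable-class]. Voxel-wise features (FCS,
#' ReHo) are scaled (z-standardization resp. mean normalization), smoothed,
#' and flattened over the in-mask voxels in the pinned scan order (native
#' column-major linear order); large-scale FC uses the row-major upper
#' triangle pair order.
#'
#' @param cohort A preprocessed [BOLDCohort-class].
#' @param spec A [featureSpec()].
#' @return A [FeatureTable-class] with the manifest as column data.
#' @export
buildFeatureTable <- function(cohort, spec = featureSpec("fcs")) {
  if (!cohort@processed)
    stop("cohort must be preprocessed first (preprocessCohort)")
  n <- nSubjects(cohort)
  dm <- cohort@dim
  coords <- cohort@coords
  mask <- array(FALSE, dm); mask[coords] <- TRUE
  vals <- vector("list", n)
  for (i in seq_len(n)) {
    x <- cohort@series[[i]]
    vals[[i]] <- switch(spec$kind,
      fcs = {
        v <- fcsCore(x, spec$rThreshold, fisher = spec$fcsScaling == "fisher")
        if (spec$fcsScaling == "map") v <- zscoreMap(v)
        smoothFlat(v, coords, dm, spec, cohort@voxelSize, mask)
      },
      reho = {
        v <- normalizeReho(as.numeric(rehoMap(x, coords, dm,
                                              spec$neighborhood)))
        smoothFlat(v, coords, dm, spec, cohort@voxelSize, mask)
      },
      lsfc = as.numeric(largescaleFC(nodeTimeseries(x, cohort@labels))))
  }
  values <- do.call(rbind, vals)
  map <- if (spec$kind == "lsfc") {
    nts <- nodeTimeseries(cohort@series[[1]], cohort@labels)
    attr(largescaleFC(nts), "map")
  } else {
    data.frame(x = coords[, 1], y = coords[, 2], z = coords[, 3])
  }
  FeatureTable(values, cohortManifest(cohort), map, spec$kind,
               geometry = list(dim = dm, voxelSize = cohort@voxelSize,
                               affine = cohort@affine, coords = coords))
}

smoothFlat <- function(v, coords, dm, spec, voxelSize, mask) {
  if (spec$smoothFwhmMm <= 0) return(v)
  vol <- vecToVolume(v, coords, dm)
  s <- gaussianSmooth(vol, spec$smoothFwhmMm, voxelSize, mask = mask,
                      renormalize = spec$renormalizeSmoothing)
  s[coords]
}
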