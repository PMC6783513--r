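## Mass-univariate group statistics: voxel-wise GLM with covariates,
## residual smoothness estimation, Monte-Carlo cluster-extent correction,
## BH-FDR for edgewise tests, and cluster-score correlations.

#' Voxel-wise two-group GLM with covariates
#'
#' Per-voxel OLS of the subject maps on `[intercept, group indicator,
#' covariates]`; the returned t statistic tests the patient - control
#' contrast. Residual maps are retained for smoothness estimation.
#'
#' @param maps Subjects x voxels matrix (one flattened in-mask map per row).
#' @param group Group label per subject (`positiveClass` coded 1).
#' @param covariates Optional data.frame of covariates (numeric columns used
#'   as given; character/factor columns coded by `model.matrix` with
#'   treatment contrasts).
#' @param positiveClass Label coded 1 in the group indicator.
#' @return List of class `GLMResult`: `t` (per voxel; `NA` where residual
#'   variance is zero), `df`, `residuals` (subjects x voxels), `design`,
#'   `flagged` (zero-variance voxel indices).
#' @export
voxelwiseGLM <- function(maps, group, covariates = NULL,
                         positiveClass = "patient") {
  group <- as.character(group)
  if (length(unique(group)) != 2L) stop("exactly two groups required")
  if (min(table(group)) < 2L) stop("need at least 2 subjects per group")
  gi <- as.numeric(group == positiveClass)
  X <- cbind(intercept = 1, group = gi)
  if (!is.null(covariates) && ncol(as.data.frame(covariates)) > 0) {
    covariates <- as.data.frame(covariates)
    flat <- vapply(covariates, function(v) length(unique(v)) < 2L, logical(1))
    if (any(flat)) {
      message("dropping constant covariate(s): ",
              paste(names(covariates)[flat], collapse = ", "))
      covariates <- covariates[!flat]
    }
    if (ncol(covariates) > 0) {
      mm <- stats::model.matrix(~ ., data = covariates)[, -1, drop = FALSE]
      X <- cbind(X, mm)
    }
  }
  QR <- qr(X)
  if (QR$rank < ncol(X)) {
    bad <- colnames(X)[QR$pivot[seq.int(QR$rank + 1L, ncol(X))]]
    stop("design is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  B <- qr.coef(QR, maps)
  res <- qr.resid(QR, maps)
  df <- nrow(maps) - ncol(X)
  if (df <= 0) stop("no residual degrees of freedom")
  sigma2 <- colSums(res^2) / df
  XtXinv <- chol2inv(qr.R(QR))
  se <- sqrt(sigma2 * XtXinv[2L, 2L])
  tstat <- B["group", ] / se
  flagged <- which(sigma2 < 1e-24)
  tstat[flagged] <- NA_real_
  structure(list(t = tstat, df = df, residuals = res, design = X,
                 flagged = flagged),
            class = "GLMResult")
}

#' Estimate residual field smoothness (per-axis FWHM)
#'
#' Classical Gaussian-field first-differences estimator: per axis `a`, with
#' `s2a` the variance of first spatial differences between in-mask neighbor
#' pairs and `s2` the point variance, the neighbor correlation is
#' `rho = 1 - s2a / (2 s2)` and
#' `FWHM_a = voxelSize * sqrt(-2 log 2 / log(rho))`. Estimates are averaged
#' over subjects; subject-axis combinations with a non-positive correlation
#' are flagged and skipped.
#'
#' @param residuals Subjects x in-mask-voxels matrix of residual maps.
#' @param coords V x 3 in-mask voxel coordinates.
#' @param dm Grid dimension.
#' @param voxelSize Voxel size in mm.
#' @return Numeric length-3 FWHM in mm (names x, y, z).
#' @export
estimateFWHM <- function(residuals, coords, dm, voxelSize = 3) {
  nV <- nrow(coords)
  memb <- integer(prod(dm))
  memb[coordsToLinear(coords, dm)] <- seq_len(nV)
  est <- matrix(NA_real_, nrow(residuals), 3L)
  for (a in 1:3) {
    nb <- coords
    nb[, a] <- nb[, a] + 1L
    ok <- nb[, a] <= dm[a]
    hit <- integer(nV)
    hit[ok] <- memb[coordsToLinear(nb[ok, , drop = FALSE], dm)]
    pair <- which(hit > 0L)
    if (length(pair) < 2L) next
    i <- pair; j <- hit[pair]
    d <- residuals[, j, drop = FALSE] - residuals[, i, drop = FALSE]
    s2a <- rowSums((d - rowMeans(d))^2) / (ncol(d) - 1L)
    s2 <- apply(residuals, 1L, var)
    rho <- 1 - s2a / (2 * s2)
    good <- rho > 0 & rho < 1
    est[good, a] <- voxelSize * sqrt(-2 * log(2) / log(rho[good]))
  }
  if (all(is.na(est))) stop("smoothness estimation failed on every axis")
  out <- colMeans(est, na.rm = TRUE)
  names(out) <- c("x", "y", "z")
  out
}

#' Monte-Carlo cluster-extent threshold (AlphaSim)
#'
#' Each iteration draws Gaussian white noise on the full grid, smooths it to
#' the given per-axis FWHM, standardizes it exactly (dividing by the known
#' per-voxel standard deviation of smoothed unit noise, so the voxel-level
#' threshold is exact under the null), thresholds two-sided at
#' `|z| > z(1 - voxelP/2)`, and records the largest connected component
#' within the mask (positive and negative voxels labeled separately, as in
#' cluster extraction). The minimum significant size is the smallest `k`
#' with empirical `P(max cluster >= k) <= clusterAlpha`.
#'
#' @param mask Logical 3D array.
#' @param fwhm Per-axis FWHM in mm (scalar or length 3), e.g. from
#'   [estimateFWHM()].
#' @param voxelSize Voxel size in mm.
#' @param voxelP Voxel-level two-sided p threshold (default 0.01).
#' @param clusterAlpha Family-wise cluster alpha (default 0.05).
#' @param nSim Monte-Carlo iterations (>= 100).
#' @param connectivity 6, 18 or 26.
#' @param seed Seed for the simulations.
#' @return List of class `ClusterCorrection`: `minSize`, `nullMaxSizes`,
#'   and the parameters.
#' @export
alphasimThreshold <- function(mask, fwhm, voxelSize = 3, voxelP = 0.01,
                              clusterAlpha = 0.05, nSim = 1000L,
                              connectivity = 26L, seed = 1L) {
  if (voxelP <= 0 || voxelP >= 1) stop("voxelP must lie in (0, 1)")
  if (nSim < 100L) stop("nSim must be at least 100")
  dm <- dim(mask)
  mask <- as.logical(mask); dim(mask) <- dm
  lin <- which(mask)
  Ks <- axisKernels(dm, fwhm, voxelSize)
  sdField <- sqrt(smoothNoiseVariance(dm, fwhm, voxelSize))
  zc <- qnorm(1 - voxelP / 2)
  maxSizes <- withSeed(seed, {
    vapply(seq_len(nSim), function(s) {
      z <- smoothWithKernels(array(rnorm(prod(dm)), dm), Ks) / sdField
      zin <- z[lin]
      mx <- 0L
      for (sgn in c(1, -1)) {
        sup <- lin[sgn * zin > zc]
        if (length(sup) > 0L) {
          lab <- labelComponents3d(sup, dm, connectivity)
          mx <- max(mx, max(tabulate(lab)))
        }
      }
      mx
    }, integer(1))
  })
  if (clusterAlpha >= 1) {
    minSize <- 1L
  } else {
    minSize <- 1L
    while (mean(maxSizes >= minSize) > clusterAlpha)
      minSize <- minSize + 1L
  }
  structure(list(minSize = minSize, nullMaxSizes = maxSizes,
                 voxelP = voxelP, clusterAlpha = clusterAlpha,
                 nSim = nSim, fwhm = fwhm, connectivity = connectivity,
                 seed = seed),
            class = "ClusterCorrection")
}

#' Apply a cluster-extent correction to a t map
#'
#' Two-sided voxel threshold at `|t| > t(1 - voxelP/2, df)`, then connected
#' components (sign-split, same connectivity as the correction) of size at
#' least the correction's minimum significant size survive.
#'
#' @param tMap Numeric vector of t values per in-mask voxel (`NA` treated as
#'   subthreshold).
#' @param df Degrees of freedom of the t statistics.
#' @param correction A `ClusterCorrection` from [alphasimThreshold()].
#' @param coords V x 3 in-mask voxel coordinates.
#' @param dm Grid dimension.
#' @param affine Optional affine for world-coordinate peaks.
#' @return Cluster data.frame as from [extractClusters()].
#' @export
applyClusterCorrection <- function(tMap, df, correction, coords, dm,
                                   affine = NULL) {
  if (df <= 0) stop("df must be positive")
  tc <- qt(1 - correction$voxelP / 2, df)
  v <- tMap
  v[is.na(v) | abs(v) <= tc] <- 0
  vol <- vecToVolume(v, coords, dm)
  extractClusters(vol, minSize = correction$minSize,
                  connectivity = correction$connectivity, affine = affine,
                  signSplit = TRUE)
}

#' Benjamini-Hochberg FDR flags
#'
#' Step-up procedure at level `q` (wraps `p.adjust(method = "BH")`).
#'
#' @param p P values in [0, 1].
#' @param q FDR level.
#' @return Logical significance flag per test.
#' @export
fdrBH <- function(p, q = 0.05) {
  if (any(p < 0 | p > 1 | is.na(p))) stop("p values must lie in [0, 1]")
  p.adjust(p, method = "BH") <= q
}

#' Correlate cluster-mean map values with a clinical score
#'
#' Averages each subject's map over the cluster voxels and correlates the
#' means with the score (Pearson; two-sided p from the t transform of r).
#' By default restricted to the patient group.
#'
#' @param maps Subjects x in-mask-voxels matrix.
#' @param clusterVoxels Column indices of the cluster's voxels, or a cluster
#'   row's `voxels` coordinate matrix together with `coords`.
#' @param scores Score per subject.
#' @param subset Logical/index subset of subjects (default all).
#' @param coords Optional V x 3 in-mask coordinates, needed when
#'   `clusterVoxels` is a coordinate matrix.
#' @return List: `r`, `p`, `n`.
#' @export
clusterScoreCorrelation <- function(maps, clusterVoxels, scores,
                                    subset = NULL, coords = NULL) {
  if (is.matrix(clusterVoxels)) {
    stopifnot(!is.null(coords))
    key <- function(m) paste(m[, 1], m[, 2], m[, 3])
    clusterVoxels <- match(key(clusterVoxels), key(coords))
    if (anyNA(clusterVoxels)) stop("cluster voxel outside the mask")
  }
  m <- rowMeans(maps[, clusterVoxels, drop = FALSE])
  if (!is.null(subset)) {
    m <- m[subset]; scores <- scores[subset]
  }
  if (length(m) < 4L) stop("need at least 4 subjects")
  if (diff(range(scores)) == 0 || diff(range(m)) == 0)
    stop("constant score or constant cluster means")
  ct <- cor.test(m, scores)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(m))
}
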