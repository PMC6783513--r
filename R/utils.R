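## Internal numerical helpers shared across modules.

.fcmvpaCache <- new.env(parent = emptyenv())

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded helpers do not disturb
#' the caller's random number stream.
#'
#' @param seed Integer seed, or `NULL` to use the current stream.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
withSeed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

## Orthonormal basis of the real Fourier modes with frequency inside
## [low, high] Hz for a series of length n sampled every tr seconds.
## Cached: the basis depends only on (n, tr, low, high).
fourierBandBasis <- function(n, tr, low, high) {
  key <- paste(n, tr, low, high, sep = "|")
  hit <- .fcmvpaCache[[key]]
  if (!is.null(hit)) return(hit)
  nyq <- 1 / (2 * tr)
  if (low <= 0 || high > nyq + 1e-12 || low >= high)
    stop("band [", low, ", ", high, "] Hz outside (0, ", nyq, "] or empty")
  kmax <- n %/% 2
  k <- seq_len(kmax)
  f <- k / (n * tr)
  keep <- k[f >= low - 1e-12 & f <= high + 1e-12]
  if (length(keep) == 0L)
    stop("no Fourier bin falls inside the requested band")
  tt <- seq_len(n) - 1
  cols <- vector("list", 2L * length(keep))
  j <- 0L
  for (kk in keep) {
    cc <- cos(2 * pi * kk * tt / n)
    j <- j + 1L
    cols[[j]] <- cc / sqrt(sum(cc^2))
    if (2L * kk < n || n %% 2L == 1L) {
      ss <- sin(2 * pi * kk * tt / n)
      j <- j + 1L
      cols[[j]] <- ss / sqrt(sum(ss^2))
    }
  }
  basis <- do.call(cbind, cols[seq_len(j)])
  .fcmvpaCache[[key]] <- basis
  basis
}

## Neighbor offsets for 3D connectivity (6 faces, 18 faces+edges, 26 full).
connectivityOffsets <- function(connectivity = 26) {
  if (!connectivity %in% c(6, 18, 26))
    stop("connectivity must be 6, 18 or 26")
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  manh <- rowSums(abs(g))
  keep <- switch(as.character(connectivity),
                 "6" = manh == 1,
                 "18" = manh >= 1 & manh <= 2,
                 "26" = manh >= 1)
  unname(g[keep, , drop = FALSE])
}

## Label connected components among voxels given by linear indices `idx`
## inside a volume of dimension `dm`. Vectorized frontier BFS; returns an
## integer component label per element of idx (labels are arbitrary ids).
labelComponents3d <- function(idx, dm, connectivity = 26) {
  nIdx <- length(idx)
  if (nIdx == 0L) return(integer(0))
  offs <- connectivityOffsets(connectivity)
  memb <- integer(prod(dm))
  memb[idx] <- seq_len(nIdx)
  coords <- arrayInd(idx, dm)
  d1 <- dm[1]; d12 <- dm[1] * dm[2]
  labels <- integer(nIdx)
  comp <- 0L
  nOff <- nrow(offs)
  for (seed in seq_len(nIdx)) {
    if (labels[seed] != 0L) next
    comp <- comp + 1L
    frontier <- seed
    labels[seed] <- comp
    while (length(frontier) > 0L) {
      fc <- coords[frontier, , drop = FALSE]
      nf <- nrow(fc)
      nb <- fc[rep(seq_len(nf), each = nOff), , drop = FALSE] +
        offs[rep(seq_len(nOff), times = nf), , drop = FALSE]
      ok <- nb[, 1] >= 1L & nb[, 1] <= dm[1] &
            nb[, 2] >= 1L & nb[, 2] <= dm[2] &
            nb[, 3] >= 1L & nb[, 3] <= dm[3]
      nb <- nb[ok, , drop = FALSE]
      lin <- nb[, 1] + (nb[, 2] - 1L) * d1 + (nb[, 3] - 1L) * d12
      ids <- memb[lin]
      ids <- unique(ids[ids != 0L])
      ids <- ids[labels[ids] == 0L]
      labels[ids] <- comp
      frontier <- ids
    }
  }
  labels
}

## 1D Gaussian convolution matrix with zero padding outside the grid.
## Returns NULL for sigma so small that the kernel is a delta.
kernelMatrix1d <- function(n, sigmaVox) {
  if (sigmaVox <= 1e-8) return(NULL)
  r <- min(max(1L, ceiling(4 * sigmaVox)), n - 1L)
  w <- exp(-((-r):r)^2 / (2 * sigmaVox^2))
  w <- w / sum(w)
  K <- matrix(0, n, n)
  for (d in (-r):r) {
    i <- seq.int(max(1L, 1L - d), min(n, n - d))
    if (length(i)) K[cbind(i, i + d)] <- w[d + r + 1L]
  }
  K
}

applyAxisKernel <- function(arr, K, axis) {
  if (is.null(K)) return(arr)
  d <- dim(arr)
  if (axis == 1L) {
    array(K %*% matrix(arr, d[1]), d)
  } else if (axis == 2L) {
    p <- aperm(arr, c(2, 1, 3))
    aperm(array(K %*% matrix(p, d[2]), d[c(2, 1, 3)]), c(2, 1, 3))
  } else {
    p <- aperm(arr, c(3, 1, 2))
    aperm(array(K %*% matrix(p, d[3]), d[c(3, 1, 2)]), c(2, 3, 1))
  }
}

fwhmToSigmaVox <- function(fwhmMm, voxelSizeMm) {
  fwhmMm / (sqrt(8 * log(2)) * voxelSizeMm)
}

## Separable Gaussian smoothing kernels per axis for a given volume dim.
axisKernels <- function(dm, fwhmMm, voxelSizeMm, square = FALSE) {
  fwhmMm <- rep_len(fwhmMm, 3L)
  lapply(1:3, function(a) {
    K <- kernelMatrix1d(dm[a], fwhmToSigmaVox(fwhmMm[a], voxelSizeMm))
    if (square && !is.null(K)) K^2 else K
  })
}

smoothWithKernels <- function(arr, Ks) {
  for (a in 1:3) arr <- applyAxisKernel(arr, Ks[[a]], a)
  arr
}

## Per-voxel variance of unit-variance white noise after zero-padded
## separable smoothing (squared-kernel trick; exact).
smoothNoiseVariance <- function(dm, fwhmMm, voxelSizeMm) {
  Ks <- axisKernels(dm, fwhmMm, voxelSizeMm, square = TRUE)
  smoothWithKernels(array(1, dm), Ks)
}

## Place a vector of in-mask values into a zero-filled volume.
vecToVolume <- function(v, coords, dm) {
  arr <- array(0, dm)
  arr[coords] <- v
  arr
}

coordsToLinear <- function(coords, dm) {
  coords[, 1] + (coords[, 2] - 1L) * dm[1] + (coords[, 3] - 1L) * dm[1] * dm[2]
}

## Column ranks of a matrix (ties -> midranks), one call per column.
columnRanks <- function(x) {
  matrix(apply(x, 2L, rank), nrow = nrow(x))
}
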