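## Temporal preprocessing of BOLD series.
##
## All operations work on plain timepoints x voxels matrices; BOLDSeries
## methods unwrap/rewrap the 4D array so geometry (grid, voxel size, affine)
## is preserved. The canonical chain is
##   discardInitial -> detrendLinear -> bandpassFilter -> regressNuisance
## and, because regressNuisance re-includes the (band-filtered) linear trend
## in its design, the full chain is an exact fixed point on already-processed
## data (projection composition; see the methods vignette).

#' Discard initial volumes
#'
#' Drops the first `n` timepoints (signal-equilibration volumes) from a BOLD
#' series or any timepoints x columns matrix (e.g. motion parameters).
#'
#' @param x A [BOLDSeries-class] or a matrix with timepoints in rows.
#' @param n Number of initial timepoints to discard (`n < timepoints`).
#' @return Same type as `x` with `n` fewer timepoints; geometry unchanged.
#' @export
setGeneric("discardInitial", function(x, n = 10L) standardGeneric("discardInitial"))

#' @rdname discardInitial
#' @export
setMethod("discardInitial", "matrix", function(x, n = 10L) {
  if (n >= nrow(x)) stop("cannot discard ", n, " of ", nrow(x), " timepoints")
  if (n == 0L) return(x)
  x[-seq_len(n), , drop = FALSE]
})

#' @rdname discardInitial
#' @export
setMethod("discardInitial", "BOLDSeries", function(x, n = 10L) {
  d <- dim(x@data)
  if (n >= d[4]) stop("cannot discard ", n, " of ", d[4], " timepoints")
  out <- x
  out@data <- x@data[, , , seq.int(n + 1L, d[4]), drop = FALSE]
  out
})

#' Remove per-column linear trends
#'
#' Least-squares residuals after projecting each column on an intercept and a
#' linear ramp; the output is orthogonal to both regressors.
#'
#' @param x Numeric matrix (timepoints x voxels) or vector.
#' @return Residual matrix of the same shape.
#' @export
detrendLinear <- function(x) {
  v <- is.null(dim(x))
  if (v) x <- matrix(x, ncol = 1L)
  n <- nrow(x)
  if (n < 3L) stop("detrending needs at least 3 timepoints")
  Q <- qr.Q(qr(cbind(1, seq_len(n))))
  out <- x - Q %*% crossprod(Q, x)
  if (v) drop(out) else out
}

#' Ideal band-pass filter
#'
#' Projects each column onto the real Fourier modes with frequency inside
#' `[low, high]` Hz (discrete-Fourier boxcar: bins strictly outside the band,
#' and always the zero-frequency bin, are zeroed). Output columns have mean
#' ~0.
#'
#' @param x Numeric matrix (timepoints x voxels) or vector.
#' @param low,high Band edges in Hz; `0 < low < high <= 1/(2 tr)`.
#' @param tr Sampling interval (repetition time) in seconds.
#' @return Filtered matrix of the same shape.
#' @export
bandpassFilter <- function(x, low = 0.01, high = 0.1, tr = 2.5) {
  v <- is.null(dim(x))
  if (v) x <- matrix(x, ncol = 1L)
  B <- fourierBandBasis(nrow(x), tr, low, high)
  out <- B %*% crossprod(B, x)
  if (v) drop(out) else out
}

#' Friston 24-parameter motion expansion
#'
#' Expands 6 rigid-body motion parameters into the 24-regressor set: the
#' parameters, their one-volume lag (first row zero-padded), and the squares
#' of both. Column order is the four blocks `[m, m_lag, m^2, m_lag^2]`, six
#' columns each.
#'
#' @param motion6 Numeric matrix with 6 columns and >= 2 rows.
#' @return Matrix with 24 named columns.
#' @export
expandFriston24 <- function(motion6) {
  motion6 <- as.matrix(motion6)
  if (ncol(motion6) != 6L) stop("expected 6 motion parameter columns")
  if (nrow(motion6) < 2L) stop("need at least 2 rows")
  lag <- rbind(0, motion6[-nrow(motion6), , drop = FALSE])
  out <- cbind(motion6, lag, motion6^2, lag^2)
  colnames(out) <- c(paste0("mot", 1:6), paste0("mot", 1:6, "_lag"),
                     paste0("mot", 1:6, "_sq"), paste0("mot", 1:6, "_lagsq"))
  out
}

#' Mean tissue signal within a mask
#'
#' @param x Timepoints x voxels matrix, or [BOLDSeries-class].
#' @param mask Logical/0-1 vector selecting columns (matrix input) or a 3D
#'   logical array (BOLDSeries input). Must select at least one voxel.
#' @return Numeric vector, one mean per timepoint.
#' @export
setGeneric("extractTissueSignal", function(x, mask) standardGeneric("extractTissueSignal"))

#' @rdname extractTissueSignal
#' @export
setMethod("extractTissueSignal", "matrix", function(x, mask) {
  idx <- which(as.logical(mask))
  if (length(idx) == 0L) stop("empty tissue mask")
  rowMeans(x[, idx, drop = FALSE])
})

#' @rdname extractTissueSignal
#' @export
setMethod("extractTissueSignal", "BOLDSeries", function(x, mask) {
  d <- dim(x@data)
  idx <- which(as.logical(mask))
  if (length(idx) == 0L) stop("empty tissue mask")
  m <- matrix(x@data, prod(d[1:3]), d[4])
  colMeans(m[idx, , drop = FALSE])
})

#' Assemble the nuisance regressor set
#'
#' Builds the standard 27-column nuisance set: Friston-24 motion expansion
#' plus CSF, white-matter and global mean signals. Any component may be
#' omitted.
#'
#' @param motion6 6-column motion matrix (already trimmed to the retained
#'   volumes), or `NULL`.
#' @param csf,wm,global Tissue mean-signal vectors, or `NULL`.
#' @return Named numeric matrix of nuisance regressors.
#' @export
makeNuisanceSet <- function(motion6 = NULL, csf = NULL, wm = NULL,
                            global = NULL) {
  parts <- list()
  if (!is.null(motion6)) parts$motion <- expandFriston24(motion6)
  if (!is.null(csf)) parts$csf <- matrix(csf, ncol = 1L,
                                         dimnames = list(NULL, "csf"))
  if (!is.null(wm)) parts$wm <- matrix(wm, ncol = 1L,
                                       dimnames = list(NULL, "wm"))
  if (!is.null(global)) parts$global <- matrix(global, ncol = 1L,
                                               dimnames = list(NULL, "global"))
  if (length(parts) == 0L) stop("no nuisance components supplied")
  do.call(cbind, unname(parts))
}

#' Regress nuisance signals out of a BOLD series
#'
#' Per-voxel OLS residuals against `[intercept, linear trend, nuisance]`.
#' Constant-zero nuisance columns are dropped with a message; a
#' rank-deficient design (after cleanup) is an error naming the collinear
#' columns. By default the trend and nuisance regressors are band-filtered
#' with the same band as the data, so the regression cannot reintroduce
#' frequencies outside the pass band.
#'
#' @param x Timepoints x voxels matrix.
#' @param nuisance Nuisance regressor matrix (rows = timepoints).
#' @param band `c(low, high)` in Hz to filter regressors with (requires
#'   `tr`), or `NULL` to use the regressors as given.
#' @param tr Repetition time in seconds (needed when `band` is given).
#' @param includeTrend Include intercept + linear ramp in the design.
#' @return Residual matrix; residuals are orthogonal to every retained
#'   regressor.
#' @export
regressNuisance <- function(x, nuisance, band = c(0.01, 0.1), tr = 2.5,
                            includeTrend = TRUE) {
  nuisance <- as.matrix(nuisance)
  if (nrow(nuisance) != nrow(x))
    stop("nuisance rows (", nrow(nuisance), ") != timepoints (", nrow(x), ")")
  if (is.null(colnames(nuisance)))
    colnames(nuisance) <- paste0("nuis", seq_len(ncol(nuisance)))
  zero <- apply(nuisance, 2L, function(col) all(abs(col) < 1e-12))
  if (any(zero)) {
    message("dropping constant-zero nuisance columns: ",
            paste(colnames(nuisance)[zero], collapse = ", "))
    nuisance <- nuisance[, !zero, drop = FALSE]
  }
  n <- nrow(x)
  design <- nuisance
  if (includeTrend) design <- cbind(trend = seq_len(n), design)
  if (!is.null(band))
    design <- bandpassFilter(design, band[1], band[2], tr)
  ## regressors whose in-band content vanished contribute nothing
  norms <- sqrt(colSums(design^2))
  tiny <- norms < 1e-9 * max(norms, 1)
  if (any(tiny)) {
    message("dropping regressors with no in-band content: ",
            paste(colnames(design)[tiny], collapse = ", "))
    design <- design[, !tiny, drop = FALSE]
    norms <- norms[!tiny]
  }
  designN <- design / rep(norms, each = n)   # unit columns for rank check
  designN <- cbind(intercept = 1 / sqrt(n), designN)
  QR <- qr(designN)
  if (QR$rank < ncol(designN)) {
    bad <- colnames(designN)[QR$pivot[seq.int(QR$rank + 1L, ncol(designN))]]
    stop("nuisance design is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  qr.resid(QR, x)
}

#' Preprocess one subject's in-mask series
#'
#' The full temporal chain: discard initial volumes (data and motion rows),
#' linear detrend, band-pass, then nuisance regression with the Friston-24
#' motion expansion and CSF / white-matter / global mean signals extracted
#' from the detrended + filtered data.
#'
#' @param x Timepoints x voxels matrix of in-mask series.
#' @param motion6 Full-length 6-column motion matrix.
#' @param tr Repetition time in seconds.
#' @param nDiscard Initial volumes to drop.
#' @param band Pass band in Hz.
#' @param csfIdx,wmIdx Column indices acting as CSF / white-matter
#'   compartments (synthetic cohorts use designated proxy regions), or `NULL`
#'   to omit.
#' @param globalSignal Include the global (whole-mask) mean regressor.
#' @param filterRegressors Band-filter the nuisance regressors too.
#' @return Residual matrix with `nrow(x) - nDiscard` rows.
#' @export
prepSeries <- function(x, motion6, tr = 2.5, nDiscard = 10L,
                       band = c(0.01, 0.1), csfIdx = NULL, wmIdx = NULL,
                       globalSignal = TRUE, filterRegressors = TRUE) {
  x <- discardInitial(x, nDiscard)
  motion6 <- discardInitial(as.matrix(motion6), nDiscard)
  x <- detrendLinear(x)
  x <- bandpassFilter(x, band[1], band[2], tr)
  nuis <- makeNuisanceSet(
    motion6 = motion6,
    csf = if (length(csfIdx)) extractTissueSignal(x, seq_len(ncol(x)) %in% csfIdx),
    wm = if (length(wmIdx)) extractTissueSignal(x, seq_len(ncol(x)) %in% wmIdx),
    global = if (globalSignal) rowMeans(x))
  regressNuisance(x, nuis, band = if (filterRegressors) band else NULL,
                  tr = tr)
}

#' Preprocess every subject of a cohort
#'
#' Applies [prepSeries()] to each subject. For simulated cohorts the last two
#' regions act as CSF and white-matter proxy compartments (synthetic block
#' "anatomy"); the global signal is the whole gray-mask mean.
#'
#' @param cohort A [BOLDCohort-class].
#' @param nDiscard Initial volumes to drop.
#' @param band Pass band in Hz.
#' @param globalSignal Regress the global mean signal.
#' @param filterRegressors Band-filter regressors with the same band.
#' @return The cohort with processed series (and trimmed motion), flagged
#'   `processed`.
#' @export
preprocessCohort <- function(cohort, nDiscard = 10L, band = c(0.01, 0.1),
                             globalSignal = TRUE, filterRegressors = TRUE) {
  if (cohort@processed) stop("cohort is already preprocessed")
  nReg <- max(cohort@labels)
  csfIdx <- which(cohort@labels == nReg)
  wmIdx <- which(cohort@labels == nReg - 1L)
  for (i in seq_len(nSubjects(cohort))) {
    cohort@series[[i]] <- prepSeries(
      cohort@series[[i]], cohort@motion[[i]], tr = cohort@tr,
      nDiscard = nDiscard, band = band, csfIdx = csfIdx, wmIdx = wmIdx,
      globalSignal = globalSignal, filterRegressors = filterRegressors)
    cohort@motion[[i]] <- discardInitial(as.matrix(cohort@motion[[i]]),
                                         nDiscard)
  }
  cohort@processed <- TRUE
  cohort
}
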