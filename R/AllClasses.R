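#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
#' @importFrom S4Vectors metadata DataFrame
#' @importFrom stats cor cor.test fft p.adjust pnorm pt qnorm qt quantile rnorm
#'   runif sd var rlnorm predict qbinom ks.test
#' @importFrom utils head read.delim write.table
NULL

#' BOLDSeries: a 4D BOLD volume with voxel geometry
#'
#' Container for a single subject's 4D (x, y, z, time) BOLD array together
#' with its voxel size in mm, repetition time in seconds, and the voxel-to-world
#' affine (NIfTI convention: the affine maps 0-based voxel indices to mm).
#'
#' @slot data 4D numeric array, voxels by time.
#' @slot voxelSize Isotropic voxel edge length in mm.
#' @slot tr Repetition time in seconds.
#' @slot affine 4x4 voxel-to-world matrix.
#' @export
setClass("BOLDSeries",
  representation(data = "array", voxelSize = "numeric",
                 tr = "numeric", affine = "matrix"))

setValidity("BOLDSeries", function(object) {
  d <- dim(object@data)
  if (length(d) != 4L) return("data must be a 4D array (x, y, z, t)")
  if (length(object@voxelSize) != 1L || object@voxelSize <= 0)
    return("voxelSize must be a positive scalar (mm)")
  if (length(object@tr) != 1L || object@tr <= 0)
    return("tr must be a positive scalar (seconds)")
  if (!all(dim(object@affine) == c(4L, 4L)) || !all(is.finite(object@affine)))
    return("affine must be a finite 4x4 matrix")
  TRUE
})

#' Construct a BOLDSeries
#'
#' @param data 4D numeric array (x, y, z, time).
#' @param voxelSize Voxel edge length in mm (isotropic).
#' @param tr Repetition time in seconds.
#' @param affine Optional 4x4 voxel-to-world affine; default centers the grid
#'   at the world origin with `voxelSize` mm scaling.
#' @return A [BOLDSeries-class] object.
#' @export
BOLDSeries <- function(data, voxelSize = 3, tr = 2.5, affine = NULL) {
  if (is.null(affine)) affine <- defaultAffine(dim(data)[1:3], voxelSize)
  new("BOLDSeries", data = data, voxelSize = voxelSize, tr = tr,
      affine = affine)
}

defaultAffine <- function(dm, voxelSize) {
  aff <- diag(c(rep(voxelSize, 3), 1))
  aff[1:3, 4] <- -(dm - 1) / 2 * voxelSize
  aff
}

#' BOLDCohort: in-mask time series for a simulated or loaded cohort
#'
#' Holds per-subject time x voxel matrices restricted to the gray-matter mask,
#' motion parameters, the cohort manifest, and shared geometry (mask voxel
#' coordinates, parcel labels, grid dimension, affine). Produced by
#' [simulateCohort()] or [loadCohort()]; preprocessed in place by
#' [preprocessCohort()].
#'
#' @slot series List of timepoints x in-mask-voxel matrices, one per subject.
#' @slot motion List of timepoints x 6 motion-parameter matrices.
#' @slot manifest Cohort manifest data.frame (one row per subject).
#' @slot coords Integer matrix (V x 3) of 1-based in-mask voxel coordinates.
#' @slot labels Integer parcel label per in-mask voxel.
#' @slot dim Integer grid dimension (length 3).
#' @slot voxelSize Voxel size in mm.
#' @slot tr Repetition time in seconds.
#' @slot affine 4x4 voxel-to-world matrix.
#' @slot gmProb Gray-matter probability volume.
#' @slot config The SimulationConfig used (empty list for loaded cohorts).
#' @slot processed Logical: has [preprocessCohort()] been applied?
#' @export
setClass("BOLDCohort",
  representation(series = "list", motion = "list", manifest = "data.frame",
                 coords = "matrix", labels = "integer", dim = "integer",
                 voxelSize = "numeric", tr = "numeric", affine = "matrix",
                 gmProb = "array", config = "list", processed = "logical"))

setValidity("BOLDCohort", function(object) {
  n <- length(object@series)
  if (nrow(object@manifest) != n)
    return("manifest rows must match number of subjects")
  if (length(object@motion) != n)
    return("motion entries must match number of subjects")
  if (anyDuplicated(object@manifest$id))
    return("subject ids must be unique")
  g <- unique(object@manifest$group)
  if (n > 0 && length(g) > 2L)
    return("group must take at most two values")
  if (ncol(object@coords) != 3L)
    return("coords must be a V x 3 matrix")
  if (length(object@labels) != nrow(object@coords))
    return("labels must have one entry per in-mask voxel")
  TRUE
})

#' FeatureTable: subjects x features with labels, covariates and index map
#'
#' Extends \linkS4class{SummarizedExperiment}: the assay holds features in rows
#' and subjects in columns, `rowData` maps each feature back to its voxel
#' coordinate (FCS/ReHo) or node pair (large-scale FC), and `colData` carries
#' the manifest (group label and covariates). Grid geometry needed for weight
#' back-projection is stored in `metadata`.
#'
#' @export
setClass("FeatureTable", contains = "SummarizedExperiment")

setValidity("FeatureTable", function(object) {
  a <- SummarizedExperiment::assay(object)
  if (anyNA(a)) return("feature matrix must not contain missing values")
  if (is.null(object$group)) return("colData must contain a 'group' column")
  md <- S4Vectors::metadata(object)
  if (is.null(md$kind)) return("metadata$kind missing")
  TRUE
})

#' Construct a FeatureTable
#'
#' @param values Numeric matrix, subjects x features.
#' @param manifest Data.frame with one row per subject; must contain `id` and
#'   `group` columns.
#' @param map Data.frame with one row per feature: voxel coordinates
#'   (`x`,`y`,`z`) for voxel-wise kinds or node pair (`node1`,`node2`) for
#'   large-scale FC.
#' @param kind One of `"fcs"`, `"lsfc"`, `"reho"`.
#' @param geometry List with grid `dim`, `voxelSize`, `affine`, and in-mask
#'   `coords` (required for back-projection of voxel-wise features).
#' @return A [FeatureTable-class].
#' @export
FeatureTable <- function(values, manifest, map, kind,
                         geometry = list()) {
  stopifnot(nrow(values) == nrow(manifest), ncol(values) == nrow(map))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = t(values)),
    rowData = map,
    colData = S4Vectors::DataFrame(manifest, row.names = manifest$id),
    metadata = list(kind = kind, geometry = geometry))
  new("FeatureTable", se)
}

#' CVResult: cross-validated classification results
#'
#' @slot foldMetrics Per-fold accuracy, sensitivity, specificity, AUC.
#' @slot metricMeans,metricSds Named means and standard deviations over folds.
#' @slot pooled Per-subject pooled predictions (id, truth, predicted, decision
#'   value, fold).
#' @slot confusion 2x2 pooled confusion matrix (rows: truth, cols: predicted).
#' @slot weights Fold-averaged discriminative weight vector in
#'   standardized-feature space.
#' @slot folds Integer test-fold assignment per subject.
#' @slot seed Seed used for fold assignment.
#' @slot config The CVConfig used.
#' @export
setClass("CVResult",
  representation(foldMetrics = "data.frame", metricMeans = "numeric",
                 metricSds = "numeric", pooled = "data.frame",
                 confusion = "matrix", weights = "numeric",
                 folds = "integer", seed = "ANY", config = "list"))

setValidity("CVResult", function(object) {
  if (sum(object@confusion) != nrow(object@pooled))
    return("confusion matrix entries must sum to the subject count")
  TRUE
})

#' PermutationResult: label-permutation significance of a CV metric
#'
#' @slot observed Observed metric for the true labels.
#' @slot metric Metric name.
#' @slot nullSamples Null metric values, one per permutation.
#' @slot pValue (N_exceed + 1) / (N_permutation + 1).
#' @slot seed Seed driving the permutations.
#' @export
setClass("PermutationResult",
  representation(observed = "numeric", metric = "character",
                 nullSamples = "numeric", pValue = "numeric", seed = "ANY"))

setValidity("PermutationResult", function(object) {
  p <- object@pValue
  if (p <= 0 || p > 1) return("pValue must lie in (0, 1]")
  TRUE
})

## ---- generics and accessors -------------------------------------------

#' @export
setGeneric("boldData", function(x) standardGeneric("boldData"))
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))
#' @export
setGeneric("repetitionTime", function(x) standardGeneric("repetitionTime"))
#' @export
setGeneric("affineMatrix", function(x) standardGeneric("affineMatrix"))
#' @export
setGeneric("nTimepoints", function(x) standardGeneric("nTimepoints"))
#' @export
setGeneric("nSubjects", function(x) standardGeneric("nSubjects"))
#' @export
setGeneric("cohortManifest", function(x) standardGeneric("cohortManifest"))
#' @export
setGeneric("maskCoords", function(x) standardGeneric("maskCoords"))
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))
#' @export
setGeneric("featureKind", function(x) standardGeneric("featureKind"))
#' @export
setGeneric("featureMap", function(x) standardGeneric("featureMap"))
#' @export
setGeneric("groupLabels", function(x) standardGeneric("groupLabels"))
#' @export
setGeneric("foldMetrics", function(x) standardGeneric("foldMetrics"))
#' @export
setGeneric("metricSummary", function(x) standardGeneric("metricSummary"))
#' @export
setGeneric("pooledPredictions", function(x) standardGeneric("pooledPredictions"))
#' @export
setGeneric("confusionCounts", function(x) standardGeneric("confusionCounts"))
#' @export
setGeneric("weightVector", function(x) standardGeneric("weightVector"))
#' @export
setGeneric("nullSamples", function(x) standardGeneric("nullSamples"))
#' @export
setGeneric("permPValueOf", function(x) standardGeneric("permPValueOf"))

#' @describeIn BOLDSeries-class The 4D data array.
#' @param x object
#' @export
setMethod("boldData", "BOLDSeries", function(x) x@data)
#' @describeIn BOLDSeries-class Voxel size in mm.
#' @export
setMethod("voxelSize", "BOLDSeries", function(x) x@voxelSize)
#' @describeIn BOLDSeries-class Repetition time in seconds.
#' @export
setMethod("repetitionTime", "BOLDSeries", function(x) x@tr)
#' @describeIn BOLDSeries-class Voxel-to-world affine.
#' @export
setMethod("affineMatrix", "BOLDSeries", function(x) x@affine)
#' @describeIn BOLDSeries-class Number of timepoints.
#' @export
setMethod("nTimepoints", "BOLDSeries", function(x) dim(x@data)[4L])
#' @export
setMethod("dim", "BOLDSeries", function(x) dim(x@data))

setMethod("show", "BOLDSeries", function(object) {
  d <- dim(object@data)
  cat("BOLDSeries: grid ", paste(d[1:3], collapse = " x "),
      ", ", d[4], " timepoints, ", object@voxelSize, " mm voxels, TR ",
      object@tr, " s\n", sep = "")
})

#' @describeIn BOLDCohort-class Number of subjects.
#' @param x object
#' @export
setMethod("nSubjects", "BOLDCohort", function(x) length(x@series))
#' @describeIn BOLDCohort-class The cohort manifest.
#' @export
setMethod("cohortManifest", "BOLDCohort", function(x) x@manifest)
#' @describeIn BOLDCohort-class In-mask voxel coordinates (V x 3, 1-based).
#' @export
setMethod("maskCoords", "BOLDCohort", function(x) x@coords)
#' @describeIn BOLDCohort-class Voxel size in mm.
#' @export
setMethod("voxelSize", "BOLDCohort", function(x) x@voxelSize)
#' @describeIn BOLDCohort-class Repetition time in seconds.
#' @export
setMethod("repetitionTime", "BOLDCohort", function(x) x@tr)
#' @describeIn BOLDCohort-class Voxel-to-world affine.
#' @export
setMethod("affineMatrix", "BOLDCohort", function(x) x@affine)

setMethod("show", "BOLDCohort", function(object) {
  tab <- table(object@manifest$group)
  cat("BOLDCohort: ", length(object@series), " subjects (",
      paste(names(tab), tab, sep = "=", collapse = ", "), "), grid ",
      paste(object@dim, collapse = " x "), ", ", nrow(object@coords),
      " in-mask voxels, ", max(object@labels), " parcels",
      if (object@processed) ", preprocessed" else ", raw", "\n", sep = "")
})

#' @describeIn FeatureTable-class Subjects x features matrix.
#' @param x object
#' @export
setMethod("featureMatrix", "FeatureTable",
          function(x) t(SummarizedExperiment::assay(x, "features")))
#' @describeIn FeatureTable-class Feature kind ("fcs", "lsfc" or "reho").
#' @export
setMethod("featureKind", "FeatureTable",
          function(x) S4Vectors::metadata(x)$kind)
#' @describeIn FeatureTable-class Feature index map (feature -> voxel or pair).
#' @export
setMethod("featureMap", "FeatureTable",
          function(x) as.data.frame(SummarizedExperiment::rowData(x)))
#' @describeIn FeatureTable-class Group label per subject.
#' @export
setMethod("groupLabels", "FeatureTable", function(x) x$group)

setMethod("show", "FeatureTable", function(object) {
  cat("FeatureTable (", S4Vectors::metadata(object)$kind, "): ",
      ncol(object), " subjects x ", nrow(object), " features\n", sep = "")
  print(table(object$group))
})

#' @describeIn CVResult-class Per-fold metric table.
#' @param x object
#' @export
setMethod("foldMetrics", "CVResult", function(x) x@foldMetrics)
#' @describeIn CVResult-class Mean and sd of each metric over folds.
#' @export
setMethod("metricSummary", "CVResult", function(x)
  data.frame(metric = names(x@metricMeans), mean = unname(x@metricMeans),
             sd = unname(x@metricSds)))
#' @describeIn CVResult-class Pooled per-subject predictions.
#' @export
setMethod("pooledPredictions", "CVResult", function(x) x@pooled)
#' @describeIn CVResult-class Pooled 2x2 confusion matrix.
#' @export
setMethod("confusionCounts", "CVResult", function(x) x@confusion)
#' @describeIn CVResult-class Fold-averaged weight vector.
#' @export
setMethod("weightVector", "CVResult", function(x) x@weights)

setMethod("show", "CVResult", function(object) {
  cat("CVResult over", max(object@folds), "folds\n")
  m <- object@metricMeans
  s <- object@metricSds
  for (nm in names(m))
    cat(sprintf("  %-12s %.3f +/- %.3f\n", nm, m[[nm]], s[[nm]]))
  cat("pooled confusion matrix (rows = truth):\n")
  print(object@confusion)
})

#' @describeIn PermutationResult-class Null metric samples.
#' @param x object
#' @export
setMethod("nullSamples", "PermutationResult", function(x) x@nullSamples)
#' @describeIn PermutationResult-class The permutation p value.
#' @export
setMethod("permPValueOf", "PermutationResult", function(x) x@pValue)

setMethod("show", "PermutationResult", function(object) {
  cat(sprintf(
    "PermutationResult: observed %s = %.4f, %d permutations, P = %.5f\n",
    object@metric, object@observed, length(object@nullSamples),
    object@pValue))
})
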