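# Shared synthetic cohorts, built lazily and cached for the whole test run.
#
# The null pool holds 200 preprocessed null cohorts (effect 0, n = 10+10,
# 24^3 grid, 12 regions) reduced to the artifacts the calibration suites
# need (large-scale FC feature table, smoothed normalized ReHo maps,
# manifest, geometry); raw series are dropped to bound memory. Effect
# cohorts (0.8, n = 20+20, default geometry) cache the FCS feature table.

.cohortCache <- new.env(parent = emptyenv())

nullPoolConfig <- function(i) {
  simulationConfig(nPerGroup = c(10L, 10L), nRegions = 12L,
                   effectStrength = 0, seed = 9000L + i)
}

nullPoolEntry <- function(i) {
  keyName <- paste0("null", i)
  hit <- .cohortCache[[keyName]]
  if (!is.null(hit)) return(hit)
  coh <- preprocessCohort(simulateCohort(nullPoolConfig(i),
                                         fullVolume = FALSE))
  ## unsmoothed ReHo maps: at this block geometry a 6 mm kernel exceeds the
  ## blocks' internal degrees of freedom, which makes cluster-extent
  ## correction degenerate (apparent FWHM far beyond the block size)
  entry <- list(
    lsfc = buildFeatureTable(coh, featureSpec("lsfc")),
    reho = featureMatrix(buildFeatureTable(
      coh, featureSpec("reho", smoothFwhmMm = 0))),
    manifest = cohortManifest(coh),
    coords = maskCoords(coh), dim = coh@dim,
    voxelSize = voxelSize(coh), labels = coh@labels)
  .cohortCache[[keyName]] <- entry
  entry
}

effectEntry <- function(seed) {
  keyName <- paste0("eff", seed)
  hit <- .cohortCache[[keyName]]
  if (!is.null(hit)) return(hit)
  cfg <- simulationConfig(nPerGroup = c(20L, 20L), effectStrength = 0.8,
                          seed = seed)
  coh <- preprocessCohort(simulateCohort(cfg, fullVolume = FALSE))
  entry <- list(
    fcs = buildFeatureTable(coh, featureSpec("fcs")),
    manifest = cohortManifest(coh),
    coords = maskCoords(coh), dim = coh@dim,
    voxelSize = voxelSize(coh), affine = affineMatrix(coh),
    labels = coh@labels,
    effectCoords = maskCoords(coh)[coh@labels == cfg$effectRegion, ,
                                   drop = FALSE])
  .cohortCache[[keyName]] <- entry
  entry
}

# A tiny raw cohort for unit tests that need series + motion.
tinyConfig <- function(seed = 1L, effectStrength = 0.5, ...) {
  # 120 volumes: after discarding 10, the 0.01-0.1 Hz band spans 50 Fourier
  # modes, comfortably more than the 29-column nuisance design
  simulationConfig(gridShape = c(16L, 16L, 16L), nPerGroup = c(4L, 5L),
                   nRegions = 6L, nTimepoints = 120L,
                   effectStrength = effectStrength, seed = seed, ...)
}
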