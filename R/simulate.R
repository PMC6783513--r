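## Synthetic rs-fMRI cohort generator.
##
## Generative model: the gray matter is a set of disjoint cuboid regions on a
## small 3D grid. Each region r carries a latent stationary AR(1) signal
## u_r(t) with unit variance; every voxel in the region observes that latent
## plus independent white noise. In patients, the designated effect region is
## additionally coupled, hub-like, to a fixed set of partner regions: each
## partner p mixes in its own shared latent g_p, and the effect region mixes
## in the average of all g_p, so that corr(effect, partner) ~ c/sqrt(P) and
## partners stay mutually uncoupled. The subject-level realized coupling c is
## effect_strength jittered multiplicatively, and clinical scores are a
## linear function of c plus noise, giving the correlation analysis a
## recoverable ground truth.

defaultScoreLink <- function() {
  data.frame(
    score = c("ISI", "PSQI", "SAS", "SDS"),
    patientMean = c(19.32, 12.45, 50.29, 55.21),
    controlMean = c(5.43, 5.77, 39.73, 40.39),
    slope = c(10, 10, 30, 30),
    noiseSd = c(2.5, 2.8, 8, 7),
    stringsAsFactors = FALSE)
}

#' Configuration for the synthetic cohort generator
#'
#' Defines the grid geometry, cohort sizes, temporal model and the injected
#' group effect. Defaults emulate the acquisition this pipeline targets
#' (240 volumes at TR 2.5 s, 3 mm voxels) on a desk-scale 24^3 grid with 64
#' cuboid 3-voxel regions.
#'
#' @param gridShape Integer vector of 3 voxel counts.
#' @param voxelSizeMm Isotropic voxel size in mm.
#' @param nTimepoints Number of volumes acquired per subject.
#' @param trS Repetition time in seconds.
#' @param nPerGroup Counts `c(patients, controls)`.
#' @param nRegions Number of cuboid gray-matter regions.
#' @param regionSize Edge length of each cuboid region, in voxels.
#' @param regionGeometry Optional data.frame (`x0`,`y0`,`z0`,`size`) placing
#'   each region explicitly (1-based corner voxel); default lays regions on a
#'   lattice with a 1-voxel gap.
#' @param effectRegion Index of the region whose whole-brain connectivity is
#'   increased in patients.
#' @param nPartners Number of partner regions coupled to the effect region.
#' @param effectStrength Latent coupling increment in [0, 1); 0 gives
#'   exchangeable groups.
#' @param couplingJitter Relative half-width of the uniform multiplicative
#'   jitter on the subject-level realized coupling.
#' @param ar1Coef Temporal AR(1) coefficient of the latent signals, in [0, 1).
#' @param noiseSd Voxel-level white noise standard deviation (latents have
#'   unit variance).
#' @param baseline Additive signal baseline.
#' @param driftSd Standard deviation of per-voxel linear drift amplitude
#'   (units of signal over the whole scan).
#' @param motionStepSd Step sd of the 6 motion-parameter random walks.
#' @param scoreLink Data.frame linking clinical scores to realized coupling:
#'   columns `score`, `patientMean`, `controlMean`, `slope`, `noiseSd`.
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @return A validated list of class `SimulationConfig`.
#' @export
simulationConfig <- function(gridShape = c(24L, 24L, 24L), voxelSizeMm = 3,
                             nTimepoints = 240L, trS = 2.5,
                             nPerGroup = c(38L, 44L),
                             nRegions = 64L, regionSize = 3L,
                             regionGeometry = NULL,
                             effectRegion = 1L, nPartners = 3L,
                             effectStrength = 0.5, couplingJitter = 0.15,
                             ar1Coef = 0.4, noiseSd = 0.45,
                             baseline = 100, driftSd = 1,
                             motionStepSd = 0.02,
                             scoreLink = defaultScoreLink(),
                             seed = 1L) {
  cfg <- list(gridShape = as.integer(gridShape), voxelSizeMm = voxelSizeMm,
              nTimepoints = as.integer(nTimepoints), trS = trS,
              nPerGroup = as.integer(nPerGroup), nRegions = as.integer(nRegions),
              regionSize = as.integer(regionSize),
              regionGeometry = regionGeometry,
              effectRegion = as.integer(effectRegion),
              nPartners = as.integer(nPartners),
              effectStrength = effectStrength,
              couplingJitter = couplingJitter,
              ar1Coef = ar1Coef, noiseSd = noiseSd, baseline = baseline,
              driftSd = driftSd, motionStepSd = motionStepSd,
              scoreLink = scoreLink, seed = as.integer(seed))
  class(cfg) <- "SimulationConfig"
  validateSimulationConfig(cfg)
  cfg
}

validateSimulationConfig <- function(cfg) {
  stopifnot(length(cfg$gridShape) == 3L, all(cfg$gridShape >= 4L),
            cfg$voxelSizeMm > 0, cfg$nTimepoints >= 4L, cfg$trS > 0,
            length(cfg$nPerGroup) == 2L, all(cfg$nPerGroup >= 1L),
            cfg$nRegions >= 2L, cfg$regionSize >= 1L,
            cfg$effectStrength >= 0, cfg$effectStrength < 1,
            cfg$ar1Coef >= 0, cfg$ar1Coef < 1, cfg$noiseSd > 0,
            cfg$nPartners >= 1L, cfg$couplingJitter >= 0,
            cfg$couplingJitter < 1)
  if (cfg$effectRegion < 1L || cfg$effectRegion > cfg$nRegions)
    stop("effectRegion must index one of the ", cfg$nRegions, " regions")
  lay <- regionLayout(cfg)
  if (cfg$nPartners > cfg$nRegions - 1L)
    stop("nPartners exceeds available regions")
  invisible(lay)
}

#' Region layout of a simulation configuration
#'
#' Lays `nRegions` disjoint cuboid blocks of edge `regionSize` on a lattice
#' within the grid (1-voxel gaps, so blocks are disconnected even under
#' 26-connectivity), or validates a user-supplied geometry.
#'
#' @param cfg A `SimulationConfig`.
#' @return Data.frame with one row per region: `region`, `x0`, `y0`, `z0`
#'   (1-based corner), `size`.
#' @export
regionLayout <- function(cfg) {
  if (!is.null(cfg$regionGeometry)) {
    lay <- cfg$regionGeometry
    stopifnot(all(c("x0", "y0", "z0", "size") %in% names(lay)),
              nrow(lay) == cfg$nRegions)
    lay$region <- seq_len(nrow(lay))
  } else {
    s <- cfg$regionSize
    starts <- lapply(cfg$gridShape, function(n) seq(2L, n - s, by = s + 1L))
    grid <- expand.grid(x0 = starts[[1]], y0 = starts[[2]], z0 = starts[[3]])
    if (nrow(grid) < cfg$nRegions)
      stop("grid too small for ", cfg$nRegions, " regions of size ", s)
    lay <- grid[seq_len(cfg$nRegions), , drop = FALSE]
    lay$size <- s
    lay$region <- seq_len(cfg$nRegions)
  }
  ## disjointness and in-grid checks
  occ <- array(FALSE, cfg$gridShape)
  for (r in seq_len(nrow(lay))) {
    xi <- lay$x0[r]:(lay$x0[r] + lay$size[r] - 1L)
    yi <- lay$y0[r]:(lay$y0[r] + lay$size[r] - 1L)
    zi <- lay$z0[r]:(lay$z0[r] + lay$size[r] - 1L)
    if (max(xi) > cfg$gridShape[1] || max(yi) > cfg$gridShape[2] ||
        max(zi) > cfg$gridShape[3] || min(xi) < 1L)
      stop("region ", r, " extends outside the grid")
    if (any(occ[xi, yi, zi])) stop("regions overlap at region ", r)
    occ[xi, yi, zi] <- TRUE
  }
  rownames(lay) <- NULL
  lay[, c("region", "x0", "y0", "z0", "size")]
}

## In-mask voxel coordinates (V x 3) and region label per voxel, in the
## package's pinned feature scan order: native column-major linear order.
regionVoxels <- function(cfg) {
  lay <- regionLayout(cfg)
  lab <- array(0L, cfg$gridShape)
  for (r in seq_len(nrow(lay))) {
    lab[lay$x0[r]:(lay$x0[r] + lay$size[r] - 1L),
        lay$y0[r]:(lay$y0[r] + lay$size[r] - 1L),
        lay$z0[r]:(lay$z0[r] + lay$size[r] - 1L)] <- lay$region[r]
  }
  lin <- which(lab != 0L)
  list(coords = arrayInd(lin, cfg$gridShape), labels = lab[lin],
       labelVolume = lab, linear = lin)
}

partnerRegions <- function(cfg) {
  p <- (cfg$effectRegion + seq_len(cfg$nPartners) - 1L) %% cfg$nRegions + 1L
  p[p != cfg$effectRegion][seq_len(cfg$nPartners)]
}

## Stationary unit-variance AR(1) columns.
ar1Matrix <- function(n, k, phi) {
  e <- matrix(rnorm(n * k), n, k)
  if (phi == 0) return(e)
  e <- e * sqrt(1 - phi^2)
  e[1L, ] <- e[1L, ] / sqrt(1 - phi^2)  # stationary start
  apply(e, 2L, function(col) as.numeric(stats::filter(col, phi, "recursive")))
}

#' Simulate one subject's BOLD data
#'
#' Draws the latent region signals, the group-specific hub coupling, voxel
#' noise, baseline + linear drift, motion random walks, and clinical scores.
#' With the same `seed`, the in-mask series are bit-identical whether or not
#' the full background volume is materialized (background noise is drawn
#' last).
#'
#' @param cfg A `SimulationConfig`.
#' @param group `"patient"` or `"control"`.
#' @param seed Integer seed for this subject.
#' @param fullVolume If `TRUE`, also return a [BOLDSeries-class] holding the
#'   full 4D grid with noise-filled background voxels.
#' @return List with `series` (timepoints x in-mask voxels), `motion`
#'   (timepoints x 6), `coupling` (realized latent coupling, 0 for controls),
#'   `scores` (named numeric), and `bold` (a `BOLDSeries`, only when
#'   `fullVolume`).
#' @export
simulateSubject <- function(cfg, group = c("patient", "control"),
                            seed = NULL, fullVolume = TRUE) {
  group <- match.arg(group)
  validateSimulationConfig(cfg)
  rv <- regionVoxels(cfg)
  nT <- cfg$nTimepoints
  nV <- nrow(rv$coords)
  P <- cfg$nPartners
  withSeed(seed, {
    ## coupling draw happens for both groups so the RNG streams stay aligned
    jit <- runif(1, 1 - cfg$couplingJitter, 1 + cfg$couplingJitter)
    coupling <- if (group == "patient")
      min(cfg$effectStrength * jit, 0.95) else 0
    lat <- ar1Matrix(nT, cfg$nRegions + P, cfg$ar1Coef)
    u <- lat[, seq_len(cfg$nRegions), drop = FALSE]
    g <- lat[, cfg$nRegions + seq_len(P), drop = FALSE]
    if (coupling > 0) {
      partners <- partnerRegions(cfg)
      eff <- cfg$effectRegion
      u[, eff] <- sqrt(1 - coupling) * u[, eff] +
        sqrt(coupling / P) * rowSums(g)
      for (j in seq_len(P))
        u[, partners[j]] <- sqrt(1 - coupling) * u[, partners[j]] +
          sqrt(coupling) * g[, j]
    }
    series <- u[, rv$labels, drop = FALSE] +
      cfg$noiseSd * matrix(rnorm(nT * nV), nT, nV)
    drift <- rnorm(nV, 0, cfg$driftSd)
    ramp <- seq(0, 1, length.out = nT)
    series <- series + outer(ramp, drift) + cfg$baseline
    motion <- apply(matrix(rnorm(nT * 6L, 0, cfg$motionStepSd), nT, 6L),
                    2L, cumsum)
    sl <- cfg$scoreLink
    intercept <- ifelse(rep(group == "patient", nrow(sl)),
                        sl$patientMean - sl$slope * cfg$effectStrength,
                        sl$controlMean)
    scores <- intercept + sl$slope * coupling + rnorm(nrow(sl)) * sl$noiseSd
    names(scores) <- sl$score
    out <- list(series = series, motion = motion, coupling = coupling,
                scores = scores, group = group)
    if (fullVolume) {
      nTot <- prod(cfg$gridShape)
      bg <- setdiff(seq_len(nTot), rv$linear)
      vol <- matrix(0, nTot, nT)
      vol[rv$linear, ] <- t(series)
      bgNoise <- matrix(rnorm(nT * length(bg)), length(bg), nT)
      bgDrift <- rnorm(length(bg), 0, cfg$driftSd)
      vol[bg, ] <- bgNoise + outer(bgDrift, ramp) + cfg$baseline
      out$bold <- BOLDSeries(array(vol, c(cfg$gridShape, nT)),
                             voxelSize = cfg$voxelSizeMm, tr = cfg$trS,
                             affine = defaultAffine(cfg$gridShape,
                                                    cfg$voxelSizeMm))
    }
    out
  })
}

#' Simulate a two-group cohort
#'
#' Generates all subjects, demographics (age, sex, education roughly matched
#' between groups), clinical scores linked to each subject's realized
#' coupling, and patient sleep-severity fields (duration, total sleep time,
#' sleep-onset latency, wake after sleep onset). Optionally writes the cohort
#' to disk as NIfTI volumes + motion text files + TSV manifest.
#'
#' @param cfg A `SimulationConfig`; `cfg$seed` drives everything.
#' @param dir Output directory, or `NULL` to keep the cohort in memory only.
#' @param fullVolume Materialize full 4D grids (forced `TRUE` when writing).
#' @return A [BOLDCohort-class]. When `dir` is given the manifest `file` and
#'   `motionFile` columns point at the written files.
#' @export
simulateCohort <- function(cfg, dir = NULL, fullVolume = !is.null(dir)) {
  validateSimulationConfig(cfg)
  if (!is.null(dir)) fullVolume <- TRUE
  rv <- regionVoxels(cfg)
  nPat <- cfg$nPerGroup[1]; nCon <- cfg$nPerGroup[2]
  n <- nPat + nCon
  group <- rep(c("patient", "control"), c(nPat, nCon))
  withSeed(cfg$seed, {
    subjectSeeds <- sample.int(.Machine$integer.max - 1L, n)
    age <- round(ifelse(group == "patient", rnorm(n, 40.61, 9.43),
                        rnorm(n, 39.91, 9.43)), 1)
    age <- pmin(pmax(age, 20), 59.9)
    sex <- ifelse(runif(n) < ifelse(group == "patient", 16 / 38, 11 / 44),
                  "M", "F")
    education <- round(pmax(ifelse(group == "patient", rnorm(n, 7.50, 3.54),
                                   rnorm(n, 8.45, 4.31)), 0), 1)
    duration <- ifelse(group == "patient",
                       round(rlnorm(n, log(35), 0.9), 1), NA_real_)
    tst <- round(ifelse(group == "patient", rnorm(n, 360, 45),
                        rnorm(n, 430, 30)))
    tst <- pmin(pmax(tst, 180), 540)
    sol <- round(pmax(ifelse(group == "patient", rnorm(n, 50, 30),
                             rnorm(n, 15, 8)), 2))
    waso <- round(pmax(ifelse(group == "patient", rnorm(n, 70, 50),
                              rnorm(n, 20, 15)), 0))
    manifest <- data.frame(
      id = sprintf("sub%03d", seq_len(n)), group = group,
      age = age, sex = sex, education = education,
      ISI = NA_real_, PSQI = NA_real_, SAS = NA_real_, SDS = NA_real_,
      duration = duration, totalSleepTime = tst, SOL = sol, WASO = waso,
      stringsAsFactors = FALSE)
    series <- vector("list", n)
    motion <- vector("list", n)
    coupling <- numeric(n)
    for (i in seq_len(n)) {
      sub <- simulateSubject(cfg, group[i], seed = subjectSeeds[i],
                             fullVolume = fullVolume)
      series[[i]] <- sub$series
      motion[[i]] <- sub$motion
      coupling[i] <- sub$coupling
      manifest[i, names(sub$scores)] <- round(sub$scores, 1)
      if (!is.null(dir)) {
        if (i == 1L) dir.create(dir, recursive = TRUE, showWarnings = FALSE)
        bf <- file.path(dir, paste0("bold_", manifest$id[i], ".nii.gz"))
        mf <- file.path(dir, paste0("motion_", manifest$id[i], ".txt"))
        writeNiftiVolume(boldData(sub$bold), cfg, bf)
        write.table(format(sub$motion, digits = 8), mf, sep = " ",
                    row.names = FALSE, col.names = FALSE, quote = FALSE)
        manifest$file[i] <- basename(bf)
        manifest$motionFile[i] <- basename(mf)
      }
    }
    manifest$coupling <- coupling
    gm <- array(0.05, cfg$gridShape)
    gm[rv$coords] <- 0.9
    if (!is.null(dir)) {
      writeNiftiVolume(gm, cfg, file.path(dir, "gm_prob.nii.gz"))
      writeNiftiVolume(rv$labelVolume, cfg,
                       file.path(dir, "parcellation.nii.gz"))
      write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                  row.names = FALSE, quote = FALSE)
      writeConfigFile(cfg, file.path(dir, "config.yaml"))
    }
    new("BOLDCohort", series = series, motion = motion, manifest = manifest,
        coords = rv$coords, labels = as.integer(rv$labels),
        dim = cfg$gridShape, voxelSize = cfg$voxelSizeMm, tr = cfg$trS,
        affine = defaultAffine(cfg$gridShape, cfg$voxelSizeMm),
        gmProb = gm, config = unclass(cfg), processed = FALSE)
  })
}

writeNiftiVolume <- function(arr, cfg, file) {
  img <- RNifti::asNifti(arr)
  nd <- length(dim(arr))
  RNifti::pixdim(img) <- c(rep(cfg$voxelSizeMm, 3), cfg$trS)[seq_len(nd)]
  aff <- defaultAffine(cfg$gridShape, cfg$voxelSizeMm)
  img <- RNifti::`qform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, file)
  invisible(file)
}

writeConfigFile <- function(cfg, file) {
  flat <- unclass(cfg)
  flat$scoreLink <- as.list(flat$scoreLink)
  flat$regionGeometry <- if (is.null(flat$regionGeometry)) NULL else
    as.list(flat$regionGeometry)
  if (requireNamespace("yaml", quietly = TRUE)) {
    yaml::write_yaml(flat, file)
  } else {
    dput(flat, file = file)
  }
  invisible(file)
}

#' Load a cohort previously written by [simulateCohort()]
#'
#' Reads the TSV manifest, the gray-matter probability and parcellation
#' volumes, the per-subject 4D NIfTIs and motion files, and restricts the
#' series to the gray-matter mask (probability strictly greater than
#' `gmProbThreshold`).
#'
#' @param dir Directory written by [simulateCohort()].
#' @param gmProbThreshold Gray-matter probability threshold (strict).
#' @return A [BOLDCohort-class].
#' @export
loadCohort <- function(dir, gmProbThreshold = 0.2) {
  manifest <- read.delim(file.path(dir, "manifest.tsv"),
                         stringsAsFactors = FALSE)
  readVol <- function(f) {
    img <- RNifti::readNifti(f)
    array(as.numeric(img), dim(img))
  }
  gm <- readVol(file.path(dir, "gm_prob.nii.gz"))
  parc <- readVol(file.path(dir, "parcellation.nii.gz"))
  mask <- makeGMMask(gm, gmProbThreshold)
  lin <- which(mask)
  coords <- arrayInd(lin, dim(mask))
  img1 <- RNifti::readNifti(file.path(dir, manifest$file[1]))
  pd <- RNifti::pixdim(img1)
  aff <- matrix(as.numeric(RNifti::xform(img1)), 4L, 4L)
  series <- vector("list", nrow(manifest))
  motion <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    arr <- as.array(RNifti::readNifti(file.path(dir, manifest$file[i])))
    nT <- dim(arr)[4]
    m <- matrix(arr, prod(dim(arr)[1:3]), nT)
    series[[i]] <- t(m[lin, , drop = FALSE])
    motion[[i]] <- as.matrix(read.table(file.path(dir,
                                                  manifest$motionFile[i])))
  }
  new("BOLDCohort", series = series, motion = motion, manifest = manifest,
      coords = coords, labels = as.integer(parc[lin]), dim = dim(mask),
      voxelSize = pd[1], tr = if (length(pd) >= 4) pd[4] else 1,
      affine = aff,
      gmProb = gm, config = list(), processed = FALSE)
}
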