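test_that("the voxel-wise GLM reduces to the classical two-sample t", {
  set.seed(1)
  n <- 24; V <- 60
  half <- matrix(rnorm(n / 2 * V), n / 2)
  group <- rep(c("patient", "control"), each = n / 2)
  # identical maps in both groups: group contrast exactly zero
  g0 <- voxelwiseGLM(rbind(half, half), group)
  expect_equal(max(abs(g0$t)), 0, tolerance = 1e-9)
  # no covariates: equals pooled-variance two-sample t at every voxel
  maps <- matrix(rnorm(n * V), n)
  g1 <- voxelwiseGLM(maps, group)
  tor <- vapply(seq_len(V), function(v)
    unname(t.test(maps[group == "patient", v], maps[group == "control", v],
                  var.equal = TRUE)$statistic), numeric(1))
  expect_equal(unname(g1$t), tor, tolerance = 1e-9)
  expect_equal(g1$df, n - 2L)
  # with covariates the df drop and the design is checked for rank
  cov <- data.frame(age = rnorm(n), sex = sample(c("M", "F"), n, TRUE),
                    education = rnorm(n))
  g2 <- voxelwiseGLM(maps, group, cov)
  expect_equal(g2$df, n - 5L)
  expect_error(voxelwiseGLM(maps, group,
                            data.frame(dup = as.numeric(group == "patient"))),
               "collinear")
})

test_that("smoothness estimation is monotone in applied smoothing", {
  set.seed(2)
  dm <- c(20L, 20L, 20L)
  coords <- as.matrix(expand.grid(1:20, 1:20, 1:20))
  colnames(coords) <- NULL
  est <- function(fwhm, reps = 4) {
    mean(vapply(seq_len(reps), function(i) {
      maps <- t(vapply(1:4, function(s) {
        as.numeric(gaussianSmooth(array(rnorm(prod(dm)), dm), fwhm, 3))
      }, numeric(prod(dm))))
      mean(estimateFWHM(maps, coords, dm, 3))
    }, numeric(1)))
  }
  e1 <- est(4); e2 <- est(7); e3 <- est(10)
  expect_lt(e1, e2)
  expect_lt(e2, e3)
})

test_that("AlphaSim matches an independent re-simulation and is monotone", {
  dm <- c(10L, 10L, 10L)
  mask <- array(TRUE, dm)
  cc <- alphasimThreshold(mask, fwhm = 0, voxelSize = 3, voxelP = 0.01,
                          nSim = 200, seed = 31)
  # independent oracle: same seed protocol, no smoothing, igraph labeling
  skip_if_not_installed("igraph")
  zc <- qnorm(1 - 0.01 / 2)
  oracle <- fcmvpa:::withSeed(31, vapply(1:200, function(s) {
    z <- array(rnorm(prod(dm)), dm)
    mx <- 0L
    for (sgn in c(1, -1)) {
      idx <- which(sgn * z > zc)
      if (length(idx))
        mx <- max(mx, max(tabulate(igraphComponents(idx, dm, 26))))
    }
    mx
  }, integer(1)))
  expect_identical(cc$nullMaxSizes, oracle)
  k <- 1L
  while (mean(oracle >= k) > 0.05) k <- k + 1L
  expect_identical(cc$minSize, k)
  # degenerate level: everything is significant
  expect_equal(alphasimThreshold(mask, 0, 3, clusterAlpha = 1,
                                 nSim = 100, seed = 1)$minSize, 1L)
  # more smoothing -> larger cluster threshold (averaged over seeds)
  th <- function(fwhm) mean(vapply(1:3, function(s)
    alphasimThreshold(mask, fwhm, 3, nSim = 100, seed = s)$minSize,
    integer(1)))
  expect_lte(th(0), th(6))
  expect_lte(th(6), th(12))
  expect_error(alphasimThreshold(mask, 6, 3, voxelP = 2), "voxelP")
  expect_error(alphasimThreshold(mask, 6, 3, nSim = 10), "nSim")
})

test_that("cluster correction keeps only large suprathreshold components", {
  dm <- c(10L, 10L, 10L)
  coords <- as.matrix(expand.grid(1:10, 1:10, 1:10))
  colnames(coords) <- NULL
  cc <- list(minSize = 5L, voxelP = 0.01, connectivity = 26L)
  class(cc) <- "ClusterCorrection"
  tmap <- numeric(1000)
  expect_equal(nrow(applyClusterCorrection(tmap, 20, cc, coords, dm)), 0L)
  # an 8-voxel block above threshold survives, a 2-voxel one does not
  vol <- array(0, dm)
  vol[2:3, 2:3, 2:3] <- 9
  vol[8, 8, 8:9] <- 9
  tmap <- vol[coords]
  out <- applyClusterCorrection(tmap, 20, cc, coords, dm)
  expect_equal(nrow(out), 1L)
  expect_equal(out$size, 8L)
  expect_error(applyClusterCorrection(tmap, 0, cc, coords, dm), "df")
})

test_that("BH-FDR flags match the step-up rule", {
  expect_identical(fdrBH(c(0.001, 0.02, 0.9)), c(TRUE, TRUE, FALSE))
  expect_identical(fdrBH(rep(1, 5)), rep(FALSE, 5))
  set.seed(4)
  for (i in 1:50) {
    p <- runif(sample(3:40, 1))^sample(1:3, 1)
    expect_identical(fdrBH(p, 0.05), bhOracle(p, 0.05))
  }
  expect_error(fdrBH(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("cluster-score correlation recovers exact and null relations", {
  set.seed(5)
  maps <- matrix(rnorm(20 * 50), 20)
  clVox <- 3:12
  means <- rowMeans(maps[, clVox])
  out <- clusterScoreCorrelation(maps, clVox, means)
  expect_equal(out$r, 1, tolerance = 1e-12)
  expect_equal(out$n, 20L)
  # permuted scores: p values approximately uniform
  ps <- vapply(1:200, function(i)
    clusterScoreCorrelation(maps, clVox, sample(means))$p, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
  expect_error(clusterScoreCorrelation(maps, clVox, rep(1, 20)), "constant")
  expect_error(clusterScoreCorrelation(maps[1:3, ], clVox, means[1:3]),
               "4 subjects")
  # coordinate-matrix form maps into mask columns
  coords <- as.matrix(expand.grid(1:5, 1:5, 1:2))
  colnames(coords) <- NULL
  out2 <- clusterScoreCorrelation(maps, coords[clVox, ], means,
                                  coords = coords)
  expect_equal(out2$r, 1, tolerance = 1e-12)
})

test_that("the injected effect survives cluster correction with power", {
  cfg <- simulationConfig(nPerGroup = c(12L, 12L), effectStrength = 0.8,
                          seed = 77)
  coh <- preprocessCohort(simulateCohort(cfg, fullVolume = FALSE))
  mf <- cohortManifest(coh)
  # unsmoothed maps: see the methods vignette on block-scale smoothness
  maps <- featureMatrix(buildFeatureTable(coh,
                                          featureSpec("fcs", smoothFwhmMm = 0)))
  glm <- voxelwiseGLM(maps, mf$group, mf[c("age", "sex", "education")])
  coords <- maskCoords(coh)
  fw <- estimateFWHM(glm$residuals, coords, coh@dim, voxelSize(coh))
  mask <- array(FALSE, coh@dim); mask[coords] <- TRUE
  cc <- alphasimThreshold(mask, fw, voxelSize(coh), nSim = 200L, seed = 7)
  cl <- applyClusterCorrection(glm$t, glm$df, cc, coords, coh@dim)
  pos <- cl[cl$sign == 1L, , drop = FALSE]
  expect_gt(nrow(pos), 0)
  effCoords <- coords[coh@labels == cfg$effectRegion, , drop = FALSE]
  # the strongest surviving positive cluster overlaps the effect region
  expect_gt(sum(key3(pos$voxels[[which.max(pos$peakValue)]]) %in%
                  key3(effCoords)), 0)
})
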