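test_that("gray-matter thresholding is strict", {
  pr <- array(0, c(3, 1, 1)); pr[] <- c(0.19, 0.20, 0.21)
  expect_identical(as.logical(makeGMMask(pr)), c(FALSE, FALSE, TRUE))
  expect_error(makeGMMask(array(1.2, c(2, 2, 2))), "\\[0, 1\\]")
  set.seed(1)
  p <- array(runif(1000), c(10, 10, 10))
  expect_equal(sum(makeGMMask(p)), sum(p > 0.2))
})

test_that("FCS matches the O(V^2) brute force and handles edge cases", {
  set.seed(42)
  n <- 150
  base <- rnorm(n)
  x <- cbind(matrix(rep(base, 4), n), matrix(rnorm(n * 20), n))
  f <- voxelwiseFCS(x, rThreshold = 0.25)
  expect_true(all(abs(f[1:4] - 3) < 0.5))
  expect_true(all(f[5:24] < 1))
  # threshold just under 1 removes everything among noisy series
  expect_true(all(voxelwiseFCS(matrix(rnorm(n * 10), n),
                               rThreshold = 1 - 1e-9) == 0))
  # brute-force equivalence, including across chunk sizes
  y <- matrix(rnorm(30 * 50), 30)
  expect_equal(voxelwiseFCS(y, 0.25), fcsOracle(y, 0.25), tolerance = 1e-10)
  expect_identical(voxelwiseFCS(y, 0.25, chunkSize = 7L),
                   voxelwiseFCS(y, 0.25, chunkSize = 512L))
  # zero-variance voxels are reported
  y[, 3] <- 5
  expect_error(voxelwiseFCS(y, 0.25), "zero-variance.*3")
})

test_that("map standardization uses the population sd and is idempotent", {
  expect_equal(zscoreMap(c(1, 2, 3)), c(-1.2247449, 0, 1.2247449),
               tolerance = 1e-6)
  z <- zscoreMap(rnorm(50, 10, 4))
  expect_equal(zscoreMap(z), z, tolerance = 1e-12)
  x <- rnorm(50)
  expect_equal(zscoreMap(3 * x - 7), zscoreMap(x), tolerance = 1e-10)
  expect_error(zscoreMap(rep(2, 10)), "constant")
})

test_that("Fisher transform evaluates, is odd, and clamps |r| >= 1", {
  expect_identical(fisherZ(0), 0)
  expect_equal(fisherZ(0.5), 0.549306, tolerance = 1e-6)
  r <- runif(20, -0.99, 0.99)
  expect_equal(fisherZ(-r), -fisherZ(r))
  expect_warning(z1 <- fisherZ(1), "clamped")
  expect_true(is.finite(z1))
})

test_that("Gaussian smoothing has the requested width and normalization", {
  vol <- array(rnorm(10^3), c(10, 10, 10))
  expect_identical(gaussianSmooth(vol, 0, 3), vol)
  # delta image: empirical FWHM within half a voxel of the request
  d <- array(0, c(21, 21, 21)); d[11, 11, 11] <- 1
  s <- gaussianSmooth(d, fwhmMm = 6, voxelSizeMm = 3)
  prof <- s[, 11, 11]
  half <- max(prof) / 2
  i1 <- min(which(prof >= half)); i2 <- max(which(prof >= half))
  xl <- i1 - 1 + (half - prof[i1 - 1]) / (prof[i1] - prof[i1 - 1])
  xr <- i2 + (prof[i2] - half) / (prof[i2] - prof[i2 + 1])
  widthMm <- (xr - xl) * 3
  expect_lt(abs(widthMm - 6), 1.5)
  # constant in-mask image is unchanged under renormalized smoothing
  m <- array(FALSE, c(10, 10, 10)); m[3:8, 3:8, 3:8] <- TRUE
  cst <- array(5, c(10, 10, 10))
  sm <- gaussianSmooth(cst, 6, 3, mask = m, renormalize = TRUE)
  expect_equal(sm[m], rep(5, sum(m)), tolerance = 1e-9)
  expect_true(all(sm[!m] == 0))
  expect_error(gaussianSmooth(vol, -1, 3), "non-negative")
})

test_that("Kendall's W matches its defining rank formula", {
  n <- 12
  mono <- seq_len(n) + 0
  expect_equal(kendallsW(cbind(mono, 2 * mono, exp(mono / 5))), 1)
  expect_equal(kendallsW(cbind(mono, rev(mono))), 0)
  set.seed(7)
  for (i in 1:20) {
    block <- matrix(sample.int(6, 15, replace = TRUE), 5, 3)
    expect_equal(kendallsW(block), kccOracle(block), tolerance = 1e-12)
  }
  expect_warning(kendallsW(cbind(rep(1, 5), rnorm(5))), "constant")
  expect_error(kendallsW(matrix(1:5, ncol = 1)), "2 series")
})

test_that("ReHo agrees with direct Kendall's W and is rank-invariant", {
  set.seed(3)
  dm <- c(6L, 6L, 6L)
  coords <- as.matrix(expand.grid(x = 1:6, y = 1:6, z = 1:6))
  colnames(coords) <- NULL
  n <- 25
  x <- matrix(rnorm(n * nrow(coords)), n)
  w <- rehoMap(x, coords, dm)
  # interior voxel equals kendallsW on its extracted 27-series block
  center <- which(coords[, 1] == 3 & coords[, 2] == 3 & coords[, 3] == 3)
  nb <- which(abs(coords[, 1] - 3) <= 1 & abs(coords[, 2] - 3) <= 1 &
              abs(coords[, 3] - 3) <= 1)
  expect_length(nb, 27)
  expect_equal(unname(w[center]), kendallsW(x[, nb]), tolerance = 1e-10)
  # monotone transform of any single series leaves W unchanged
  x2 <- x; x2[, center] <- exp(2 * x2[, center] + 1)
  expect_equal(as.numeric(rehoMap(x2, coords, dm)), as.numeric(w),
               tolerance = 1e-12)
  # identical monotone series everywhere: raw 1, normalized 1
  xm <- matrix(rep(seq_len(n), nrow(coords)), n)
  wm <- rehoMap(xm, coords, dm)
  expect_equal(as.numeric(wm), rep(1, nrow(coords)), tolerance = 1e-12)
  expect_equal(mean(normalizeReho(as.numeric(w))), 1, tolerance = 1e-12)
})

test_that("node series and large-scale FC match brute-force loops", {
  set.seed(11)
  x <- matrix(rnorm(40 * 12), 40)
  labels <- c(1, 1, 2, 3, 3, 3, 4, 4, 5, 5, 5, 5)
  nts <- nodeTimeseries(x, labels)
  expect_equal(nts[2, ], x[, 3], ignore_attr = TRUE)
  expect_equal(nts[1, ], (x[, 1] + x[, 2]) / 2, ignore_attr = TRUE)
  for (l in 1:5)
    expect_equal(nts[l, ], colMeans(t(x[, labels == l, drop = FALSE])),
                 ignore_attr = TRUE)
  expect_error(nodeTimeseries(x, c(labels[-1], 7)), "empty node")
  # large-scale FC: N = 2 closed form, N = 5 brute force, row-major order
  n2 <- nts[1:2, ]
  expect_equal(as.numeric(largescaleFC(n2)), atanh(cor(n2[1, ], n2[2, ])))
  v <- largescaleFC(nts)
  expect_length(v, 10)
  mp <- attr(v, "map")
  expect_equal(mp$node1[1:4], c(1, 1, 1, 1))
  expect_equal(mp$node2[1:4], 2:5)
  for (k in seq_len(10))
    expect_equal(v[k], atanh(cor(nts[mp$node1[k], ], nts[mp$node2[k], ])),
                 ignore_attr = TRUE)
  expect_error(largescaleFC(rbind(rep(1, 40), rnorm(40))), "constant")
})

test_that("feature tables flatten consistently and round-trip the map", {
  cfg <- tinyConfig(seed = 2)
  coh <- preprocessCohort(simulateCohort(cfg, fullVolume = FALSE))
  ft <- buildFeatureTable(coh, featureSpec("fcs"))
  expect_s4_class(ft, "FeatureTable")
  expect_equal(dim(featureMatrix(ft)), c(9L, nrow(maskCoords(coh))))
  expect_identical(featureKind(ft), "fcs")
  # index map is a bijection: re-extracting from the back-projected map
  # reproduces every feature value
  X <- featureMatrix(ft)
  mp <- as.matrix(featureMap(ft))
  vol <- vectorToMap(X[4, ], maskCoords(coh), coh@dim)
  expect_equal(vol[mp], unname(X[4, ]))
  expect_equal(max(vol), max(X[4, ]))
  # per-voxel affine rescaling of the input leaves FCS and ReHo untouched
  x <- coh@series[[1]]
  a <- runif(ncol(x), 0.5, 2); b <- rnorm(ncol(x))
  xr <- sweep(sweep(x, 2, a, "*"), 2, b, "+")
  expect_equal(voxelwiseFCS(xr, 0.25), voxelwiseFCS(x, 0.25),
               tolerance = 1e-9)
  expect_equal(as.numeric(rehoMap(xr, maskCoords(coh), coh@dim)),
               as.numeric(rehoMap(x, maskCoords(coh), coh@dim)),
               tolerance = 1e-9)
  # lsfc table has the pair dimensionality
  ft2 <- buildFeatureTable(coh, featureSpec("lsfc"))
  expect_equal(nrow(ft2), 6 * 5 / 2)
})
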