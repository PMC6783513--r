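test_that("stratified folds deal each class into near-equal test blocks", {
  labels <- rep(c("patient", "control"), c(38, 44))
  f <- stratifiedFolds(labels, k = 5, seed = 1)
  pat <- table(f[labels == "patient"])
  con <- table(f[labels == "control"])
  expect_equal(sort(as.integer(pat), decreasing = TRUE), c(8, 8, 8, 7, 7))
  expect_equal(sort(as.integer(con), decreasing = TRUE), c(9, 9, 9, 9, 8))
  # partition: every subject in exactly one test block
  expect_equal(sort(unique(f)), 1:5)
  expect_length(f, 82)
  f2 <- stratifiedFolds(rep(c("a", "b"), each = 10), k = 5, seed = 3)
  expect_true(all(table(f2, rep(c("a", "b"), each = 10)) == 2))
  expect_error(stratifiedFolds(rep(c("a", "b"), c(3, 10)), k = 5), "fewer")
  # reproducible and seed-sensitive
  expect_identical(stratifiedFolds(labels, 5, seed = 9),
                   stratifiedFolds(labels, 5, seed = 9))
})

test_that("fold fitting separates separable data and is PCA-invariant", {
  set.seed(5)
  n <- 30
  y <- rep(c("control", "patient"), each = n / 2)
  X <- matrix(rnorm(n * 2), n)
  X[y == "patient", 1] <- X[y == "patient", 1] + 6
  fit <- fitFold(X, y, X, cvConfig())
  expect_identical(fit$predicted, y)
  # weight points from the control centroid toward the patient centroid
  expect_gt(fit$weights[1], 0)
  expect_gt(abs(fit$weights[1]), abs(fit$weights[2]))

  # all-component PCA is a pure rotation: decision values match without it
  Xw <- matrix(rnorm(24 * 40), 24)
  yw <- rep(c("control", "patient"), 12)
  Xt <- matrix(rnorm(10 * 40), 10)
  d1 <- fitFold(Xw, yw, Xt, cvConfig(usePCA = TRUE))$decision
  d2 <- fitFold(Xw, yw, Xt, cvConfig(usePCA = FALSE))$decision
  expect_lt(max(abs(d1 - d2)), 1e-6)

  # duplicated feature columns share the back-projected weight equally
  Xd <- cbind(Xw, Xw[, 1])
  wd <- fitFold(Xd, yw, cbind(Xt, Xt[, 1]), cvConfig())$weights
  expect_equal(wd[1], wd[41], tolerance = 1e-8)

  # no leakage: fitted parameters are functions of the training rows only
  w1 <- fitFold(Xw, yw, Xt, cvConfig(seed = 1))$weights
  w2 <- fitFold(Xw, yw, Xt + 100, cvConfig(seed = 1))$weights
  expect_identical(w1, w2)
  expect_error(fitFold(Xw, rep("patient", 24), Xt, cvConfig()),
               "single class")
})

test_that("cross-validation aggregates metrics, weights and predictions", {
  set.seed(8)
  n <- 30
  manifest <- data.frame(id = sprintf("s%02d", 1:n),
                         group = rep(c("patient", "control"), each = n / 2))
  X <- matrix(rnorm(n * 5), n)
  X[manifest$group == "patient", 3] <- X[manifest$group == "patient", 3] + 8
  ft <- FeatureTable(X, manifest, data.frame(f = 1:5), "fcs")
  cv <- runCV(ft, cvConfig(seed = 2))
  expect_equal(unname(cv@metricMeans[c("accuracy", "sensitivity",
                                       "specificity", "auc")]),
               rep(1, 4))
  expect_equal(sum(confusionCounts(cv)), n)
  expect_equal(diag(confusionCounts(cv)), c(control = 15, patient = 15))
  pooled <- pooledPredictions(cv)
  expect_identical(pooled$predicted, pooled$truth)
  expect_equal(which.max(abs(weightVector(cv))), 3L)
  # sensitivity counts patients: confusion row/col conventions
  expect_equal(cv@confusion["patient", "patient"], 15L)
})

test_that("rank AUC equals the ROC oracle", {
  skip_if_not_installed("pROC")
  set.seed(13)
  for (i in 1:10) {
    dv <- rnorm(30)
    y <- sample(rep(c("patient", "control"), 15))
    a1 <- fcmvpa:::rankAUC(dv, y, "patient")
    a2 <- as.numeric(suppressMessages(
      pROC::auc(pROC::roc(response = y, predictor = dv,
                          levels = c("control", "patient"),
                          direction = "<"))))
    expect_equal(a1, a2, tolerance = 1e-12)
  }
})

test_that("permutation p values follow the counting formula", {
  expect_equal(permPValue(0.9, rep(0.5, 1000)), 1 / 1001)
  expect_lt(permPValue(0.9, rep(0.5, 1000)), 0.001)
  expect_equal(permPValue(0.1, seq(0.2, 0.9, length.out = 50)), 1)
  # ties count as exceedances
  expect_equal(permPValue(0.5, c(0.5, 0.4)), 2 / 3)

  # end-to-end on a strongly separated toy table
  set.seed(4)
  n <- 20
  manifest <- data.frame(id = sprintf("s%02d", 1:n),
                         group = rep(c("patient", "control"), each = n / 2))
  X <- matrix(rnorm(n * 4), n)
  X[manifest$group == "patient", 1] <- X[manifest$group == "patient", 1] + 10
  ft <- FeatureTable(X, manifest, data.frame(f = 1:4), "fcs")
  pr <- permutationTest(ft, cvConfig(seed = 6, nPermutations = 49))
  expect_equal(pr@observed, 1)
  expect_equal(permPValueOf(pr), 1 / 50)
  expect_length(nullSamples(pr), 49)
})

test_that("confound residualization removes exactly the covariate", {
  set.seed(9)
  n <- 24
  manifest <- data.frame(id = sprintf("s%02d", 1:n),
                         group = rep(c("patient", "control"), each = n / 2),
                         PSQI = rnorm(n, 10, 3))
  X <- cbind(3 * manifest$PSQI + 2,          # pure covariate
             rnorm(n),                        # noise
             rnorm(n) + 0.5 * manifest$PSQI)  # mixed
  ft <- FeatureTable(X, manifest, data.frame(f = 1:3), "fcs")
  rt <- residualizeConfound(ft, "PSQI")
  Xr <- featureMatrix(rt)
  expect_lt(max(abs(Xr[, 1])), 1e-9)
  expect_true(all(abs(cor(Xr[, 2:3], manifest$PSQI)) < 1e-9))
  expect_equal(Xr, unname(olsResidOracle(X, cbind(1, manifest$PSQI))),
               ignore_attr = TRUE, tolerance = 1e-9)
  manifest$flat <- 1
  ftc <- FeatureTable(X, manifest, data.frame(f = 1:3), "fcs")
  expect_error(residualizeConfound(ftc, "flat"), "constant")
})

test_that("severity filtering implements the inclusion predicate", {
  mk <- function(...) data.frame(id = "p1", group = "patient", ...)
  kept <- filterSeverity(mk(duration = 12, totalSleepTime = 380, SOL = 50,
                            WASO = 10))
  expect_equal(nrow(kept), 1L)
  gone <- filterSeverity(mk(duration = 3, totalSleepTime = 380, SOL = 50,
                            WASO = 50))
  expect_equal(nrow(gone), 0L)
  # controls pass through untouched, missing fields exclude with warning
  m <- data.frame(id = c("p1", "c1"), group = c("patient", "control"),
                  duration = c(NA, NA), totalSleepTime = c(300, NA),
                  SOL = c(50, NA), WASO = c(50, NA))
  expect_warning(out <- filterSeverity(m), "missing severity")
  expect_identical(out$id, "c1")
  # random manifests match the brute-force predicate
  set.seed(2)
  for (i in 1:20) {
    n <- 15
    m <- data.frame(id = seq_len(n),
                    group = sample(c("patient", "control"), n, TRUE),
                    duration = sample(c(2, 8, 40), n, TRUE),
                    totalSleepTime = sample(c(300, 380, 450), n, TRUE),
                    SOL = sample(c(10, 50), n, TRUE),
                    WASO = sample(c(10, 50), n, TRUE))
    want <- m$group == "control" |
      (m$duration > 6 & m$totalSleepTime <= 390 &
         (m$SOL > 45 | m$WASO > 45 | m$SOL + m$WASO > 60))
    expect_identical(filterSeverity(m)$id, m$id[want])
  }
})
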