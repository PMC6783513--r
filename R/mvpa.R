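## Cross-validated linear-SVM MVPA with permutation significance.

#' Cross-validation settings
#'
#' @param k Number of folds (each class is dealt into k nearly equal test
#'   blocks, an 80/20 train/test split at k = 5).
#' @param seed Seed for the fold assignment (and permutation stream).
#' @param nPermutations Label permutations for [permutationTest()].
#' @param svmCost Soft-margin cost C of the linear SVM.
#' @param positiveClass Label treated as positive (sensitivity numerator).
#' @param usePCA Apply all-component PCA after train standardization (a pure
#'   rotation; decision values are unchanged up to numerical tolerance).
#' @param residualizeWithin Optional covariate name residualized out of every
#'   feature using train-fit slopes within each fold (leakage-free variant of
#'   [residualizeConfound()]).
#' @return A validated list of class `CVConfig`.
#' @export
cvConfig <- function(k = 5L, seed = 1L, nPermutations = 1000L, svmCost = 1,
                     positiveClass = "patient", usePCA = TRUE,
                     residualizeWithin = NULL) {
  stopifnot(k >= 2L, svmCost > 0, nPermutations >= 1L)
  structure(list(k = as.integer(k), seed = seed,
                 nPermutations = as.integer(nPermutations),
                 svmCost = svmCost, positiveClass = positiveClass,
                 usePCA = usePCA, residualizeWithin = residualizeWithin),
            class = "CVConfig")
}

#' Stratified fold assignment
#'
#' Within each class, subjects are shuffled and dealt into `k` nearly equal
#' test blocks (sizes differ by at most one); every subject lands in exactly
#' one test block.
#'
#' @param labels Class label per subject.
#' @param k Number of folds.
#' @param seed Seed for the shuffle.
#' @return Integer test-fold id (1..k) per subject.
#' @export
stratifiedFolds <- function(labels, k = 5L, seed = NULL) {
  labels <- as.character(labels)
  fold <- integer(length(labels))
  withSeed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      n <- length(idx)
      if (n < k) stop("class '", cl, "' has fewer members (", n,
                      ") than folds (", k, ")")
      sizes <- rep(n %/% k, k)
      extra <- n %% k
      if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
      fold[sample(idx)] <- rep(seq_len(k), times = sizes)
    }
  })
  fold
}

## Train-only standardization; zero-variance features are zeroed out.
foldStandardizer <- function(train) {
  mu <- colMeans(train)
  sdv <- sqrt(colSums((train - rep(mu, each = nrow(train)))^2) /
              (nrow(train) - 1L))
  dead <- sdv < 1e-12
  sdv[dead] <- 1
  list(mu = mu, sd = sdv, dead = dead,
       apply = function(x) {
         z <- (x - rep(mu, each = nrow(x))) / rep(sdv, each = nrow(x))
         if (any(dead)) z[, dead] <- 0
         z
       })
}

#' Fit one cross-validation fold
#'
#' Standardizes features with train-fit mean/sd (zero-variance features are
#' zeroed and recorded), optionally rotates with all-component PCA fit on the
#' training rows, trains a linear soft-margin SVM, and pushes the test rows
#' through the identical transform chain. The weight vector is returned in
#' standardized-feature space (back-rotated through the PCA), oriented so
#' positive weights point toward the positive class.
#'
#' @param trainX,trainY Training features (rows = subjects) and labels.
#' @param testX Test features.
#' @param cfg A [cvConfig()].
#' @return List with `predicted` (character), `decision` (positive-class
#'   decision values), `weights` (standardized-space weight vector),
#'   `deadFeatures` (indices zeroed for zero train variance).
#' @export
fitFold <- function(trainX, trainY, testX, cfg = cvConfig()) {
  trainY <- as.character(trainY)
  classes <- unique(trainY)
  if (length(classes) < 2L) stop("training set contains a single class")
  pos <- cfg$positiveClass
  if (!pos %in% classes) stop("positive class '", pos, "' not in training set")
  std <- foldStandardizer(trainX)
  Ztr <- std$apply(trainX)
  Zte <- std$apply(testX)
  if (isTRUE(cfg$usePCA)) {
    sv <- svd(Ztr, nu = 0)
    rot <- sv$v
    Ztr <- Ztr %*% rot
    Zte <- Zte %*% rot
  }
  fit <- e1071::svm(Ztr, factor(trainY), kernel = "linear",
                    cost = cfg$svmCost, scale = FALSE)
  wpc <- as.numeric(crossprod(fit$coefs, fit$SV))
  b <- -fit$rho
  dtr <- as.numeric(Ztr %*% wpc) + b
  s <- if (mean(dtr[trainY == pos]) >= mean(dtr[trainY != pos])) 1 else -1
  decision <- s * (as.numeric(Zte %*% wpc) + b)
  neg <- setdiff(classes, pos)[1]
  predicted <- ifelse(decision > 0, pos, neg)
  w <- if (isTRUE(cfg$usePCA)) as.numeric(rot %*% wpc) else wpc
  list(predicted = predicted, decision = decision, weights = s * w,
       deadFeatures = which(std$dead))
}

## Mann-Whitney AUC of decision values for the positive class.
rankAUC <- function(decision, truth, pos) {
  isPos <- truth == pos
  nPos <- sum(isPos); nNeg <- sum(!isPos)
  if (nPos == 0L || nNeg == 0L) return(NA_real_)
  r <- rank(decision)
  (sum(r[isPos]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' Run stratified k-fold cross-validated classification
#'
#' Per fold: accuracy, sensitivity (positive = patient), specificity and AUC
#' on that fold's test block; metric means and sds over folds; weight vectors
#' averaged over folds; pooled per-subject predictions assembled into one
#' confusion matrix. A fold whose test block contains a single class yields
#' an undefined AUC, recorded as missing and excluded from the mean with a
#' warning.
#'
#' @param ft A [FeatureTable-class].
#' @param cfg A [cvConfig()].
#' @return A [CVResult-class].
#' @export
runCV <- function(ft, cfg = cvConfig()) {
  X <- featureMatrix(ft)
  y <- as.character(groupLabels(ft))
  cov <- if (!is.null(cfg$residualizeWithin)) {
    v <- ft[[cfg$residualizeWithin]]
    if (is.null(v) || anyNA(v))
      stop("covariate '", cfg$residualizeWithin, "' missing for some subjects")
    v
  }
  runCVCore(X, y, ft$id, cfg, covariate = cov)
}

runCVCore <- function(X, y, ids, cfg, covariate = NULL) {
  pos <- cfg$positiveClass
  neg <- setdiff(unique(y), pos)[1]
  folds <- stratifiedFolds(y, cfg$k, cfg$seed)
  n <- length(y)
  predicted <- character(n)
  decision <- numeric(n)
  wsum <- numeric(ncol(X))
  fm <- vector("list", cfg$k)
  for (f in seq_len(cfg$k)) {
    te <- folds == f
    Xtr <- X[!te, , drop = FALSE]
    Xte <- X[te, , drop = FALSE]
    ytr <- y[!te]
    if (!is.null(covariate)) {
      ## train-fit covariate slopes applied to both blocks (no leakage)
      Dtr <- cbind(1, covariate[!te])
      B <- qr.coef(qr(Dtr), Xtr)
      Xtr <- Xtr - Dtr %*% B
      Xte <- Xte - cbind(1, covariate[te]) %*% B
    }
    fit <- fitFold(Xtr, ytr, Xte, cfg)
    predicted[te] <- fit$predicted
    decision[te] <- fit$decision
    wsum <- wsum + fit$weights
    truth <- y[te]
    fm[[f]] <- data.frame(
      fold = f,
      accuracy = mean(fit$predicted == truth),
      sensitivity = if (any(truth == pos))
        mean(fit$predicted[truth == pos] == pos) else NA_real_,
      specificity = if (any(truth == neg))
        mean(fit$predicted[truth == neg] == neg) else NA_real_,
      auc = rankAUC(fit$decision, truth, pos),
      nTest = sum(te))
  }
  fm <- do.call(rbind, fm)
  if (anyNA(fm$auc))
    warning("single-class test block: AUC undefined in ",
            sum(is.na(fm$auc)), " fold(s), excluded from the mean")
  metrics <- c("accuracy", "sensitivity", "specificity", "auc")
  mm <- vapply(fm[metrics], mean, numeric(1), na.rm = TRUE)
  ms <- vapply(fm[metrics], sd, numeric(1), na.rm = TRUE)
  pooled <- data.frame(id = ids, truth = y, predicted = predicted,
                       decision = decision, fold = folds,
                       stringsAsFactors = FALSE)
  conf <- table(factor(y, levels = c(neg, pos)),
                factor(predicted, levels = c(neg, pos)))
  conf <- matrix(as.integer(conf), 2L, 2L,
                 dimnames = list(truth = c(neg, pos),
                                 predicted = c(neg, pos)))
  new("CVResult", foldMetrics = fm, metricMeans = mm, metricSds = ms,
      pooled = pooled, confusion = conf, weights = wsum / cfg$k,
      folds = as.integer(folds), seed = cfg$seed, config = unclass(cfg))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Permutation p value
#'
#' `(N_exceed + 1) / (N_permutation + 1)` where `N_exceed` counts null
#' samples greater than or equal to the observed value (ties exceed).
#'
#' @param observed Observed metric.
#' @param nullSamples Null metric samples.
#' @return The permutation p value, in (0, 1].
#' @export
permPValue <- function(observed, nullSamples) {
  (sum(nullSamples >= observed) + 1) / (length(nullSamples) + 1)
}

#' Label-permutation significance of a CV metric
#'
#' Each iteration applies one global permutation of the class labels (every
#' training set therefore inherits permuted labels) and reruns the entire
#' stratified k-fold cross-validation, building the null distribution of the
#' metric mean.
#'
#' @param ft A [FeatureTable-class].
#' @param cfg A [cvConfig()]; `cfg$nPermutations` iterations are run and
#'   `cfg$seed` drives both the observed fold split and the permutations.
#' @param metric One of `"accuracy"`, `"sensitivity"`, `"specificity"`,
#'   `"auc"`.
#' @return A [PermutationResult-class].
#' @export
permutationTest <- function(ft, cfg = cvConfig(), metric = "accuracy") {
  stopifnot(metric %in% c("accuracy", "sensitivity", "specificity", "auc"))
  X <- featureMatrix(ft)
  y <- as.character(groupLabels(ft))
  ids <- ft$id
  obs <- runCVCore(X, y, ids, cfg)@metricMeans[[metric]]
  nulls <- withSeed(cfg$seed, {
    vapply(seq_len(cfg$nPermutations), function(b) {
      yp <- sample(y)
      subCfg <- cfg
      subCfg$seed <- sample.int(.Machine$integer.max - 1L, 1L)
      suppressWarnings(runCVCore(X, yp, ids, subCfg)@metricMeans[[metric]])
    }, numeric(1))
  })
  new("PermutationResult", observed = obs, metric = metric,
      nullSamples = nulls, pValue = permPValue(obs, nulls),
      seed = cfg$seed)
}

residualizeCore <- function(values, covariate) {
  D <- cbind(1, covariate)
  QR <- qr(D)
  qr.resid(QR, values)
}

#' Remove a covariate from every feature by linear regression
#'
#' Replaces each feature column by the residual of its least-squares fit on
#' `[intercept, covariate]` across the full sample, so the resulting features
#' have zero sample correlation with the covariate. (Fitting on the full
#' sample mirrors the published procedure; it leaks the covariate
#' distribution across CV folds — a leakage-free per-fold variant is
#' available via `cvConfig(residualizeWithin = )`.)
#'
#' @param ft A [FeatureTable-class].
#' @param covariate Name of a column of the manifest (e.g. `"PSQI"`).
#' @return A new [FeatureTable-class] with residualized features.
#' @export
residualizeConfound <- function(ft, covariate = "PSQI") {
  cv <- ft[[covariate]]
  if (is.null(cv) || anyNA(cv))
    stop("covariate '", covariate, "' missing for some subjects")
  if (diff(range(cv)) == 0) stop("constant covariate")
  values <- residualizeCore(featureMatrix(ft), cv)
  FeatureTable(values,
               as.data.frame(SummarizedExperiment::colData(ft)),
               featureMap(ft), featureKind(ft),
               geometry = S4Vectors::metadata(ft)$geometry)
}

#' Apply sleep-severity inclusion criteria to a manifest
#'
#' Patients are retained iff duration > `durationMonths` AND total sleep
#' time <= `tstMax` minutes AND (SOL > `solMin` OR WASO > `wasoMin` OR
#' SOL + WASO > `solWasoMin`); controls are untouched. Patients with missing
#' severity fields are excluded with a warning.
#'
#' @param manifest Cohort manifest with `group`, `duration` (months),
#'   `totalSleepTime` (minutes), `SOL`, `WASO` (minutes).
#' @param durationMonths,tstMax,solMin,wasoMin,solWasoMin Criterion
#'   thresholds (defaults: > 6 months, <= 390 min i.e. 6.5 h, > 45, > 45,
#'   > 60 min).
#' @return The filtered manifest.
#' @export
filterSeverity <- function(manifest, durationMonths = 6, tstMax = 390,
                           solMin = 45, wasoMin = 45, solWasoMin = 60) {
  pat <- manifest$group == "patient"
  need <- c("duration", "totalSleepTime", "SOL", "WASO")
  vals <- manifest[need]
  miss <- pat & Reduce(`|`, lapply(vals, is.na))
  if (any(miss))
    warning("excluding ", sum(miss), " patient(s) with missing severity fields")
  keep <- !pat | (!miss &
    manifest$duration > durationMonths &
    manifest$totalSleepTime <= tstMax &
    (manifest$SOL > solMin | manifest$WASO > wasoMin |
       manifest$SOL + manifest$WASO > solWasoMin))
  keep[is.na(keep)] <- FALSE
  manifest[keep, , drop = FALSE]
}
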