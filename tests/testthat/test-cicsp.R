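test_that("class covariances are unit-trace averages of normalized trial covariances", {
  set.seed(91)
  # i.i.d. unit-variance noise: covariance approaches I/C
  C <- 10
  x1 <- matrix(rnorm(C * 1e4), C)
  x2 <- matrix(rnorm(C * 1e4), C)
  ts <- TrialSet(list(x1, x2), c("left", "right"), paste0("ch", 1:C), 250)
  covs <- classCovariances(ts)
  expect_named(covs, c("left", "right"))
  expect_equal(sum(diag(covs$left)), 1, tolerance = 1e-12)
  expect_equal(sum(diag(covs$right)), 1, tolerance = 1e-12)
  expect_equal(diag(covs$left), rep(1 / C, C), tolerance = 0.1,
               ignore_attr = TRUE)

  # duplicating the trial set leaves the class covariances unchanged
  ts2 <- TrialSet(c(list(x1, x2), list(x1, x2)),
                  rep(c("left", "right"), 2), paste0("ch", 1:C), 250)
  expect_equal(classCovariances(ts2), covs, tolerance = 1e-12)

  oneClass <- TrialSet(list(x1), "left", paste0("ch", 1:C), 250)
  expect_error(classCovariances(oneClass), "two classes")
})

test_that("CSP solves the simultaneous diagonalization", {
  # 2x2 closed form: axes are the filters, eigenvalues 2/3 and 1/3
  fb <- solveCSP(diag(c(2, 1)) / 3, diag(c(1, 2)) / 3)
  expect_equal(cspEigenvalues(fb), c(2 / 3, 1 / 3), tolerance = 1e-6)
  W <- spatialFilters(fb)
  expect_equal(abs(W) %*% c(1, 1), matrix(sqrt(1), 2), tolerance = 1e-6)
  expect_equal(abs(W[1, 2]), 0, tolerance = 1e-6)
  expect_equal(abs(W[2, 1]), 0, tolerance = 1e-6)

  # equal covariances: no direction separates, all eigenvalues 1/2
  set.seed(92)
  A <- randomSPD(6)
  expect_equal(cspEigenvalues(solveCSP(A, A)), rep(0.5, 6),
               tolerance = 1e-8)

  # W (C1+C2) W' = I on random SPD pairs
  for (i in 1:5) {
    C1 <- randomSPD(8); C2 <- randomSPD(8)
    fb <- solveCSP(C1, C2)
    W <- spatialFilters(fb)
    expect_equal(W %*% (C1 + C2) %*% t(W), diag(8), tolerance = 1e-6,
                 ignore_attr = TRUE)
    expect_true(all(diff(cspEigenvalues(fb)) <= 1e-12))
  }
})

test_that("log-variance features are normalized shares, invariant to scale", {
  set.seed(93)
  Z <- matrix(rnorm(4 * 200), 4)
  lam <- logvarFeatures(Z)
  expect_equal(sum(exp(lam)), 1, tolerance = 1e-12)
  expect_equal(logvarFeatures(10 * Z), lam, tolerance = 1e-12)

  # two rows with equal power give log(0.5) each
  equal <- rbind(sin(1:100), cos(1:100) * sqrt(sum(sin(1:100)^2) /
                                               sum(cos(1:100)^2)))
  expect_equal(logvarFeatures(equal), rep(log(0.5), 2), tolerance = 1e-9)

  expect_error(logvarFeatures(matrix(1, 2, 1)), "2 samples")
})

test_that("CICSP training produces the contracted feature geometry", {
  cfg <- fastConfig(seed = 94)
  trials <- preprocessMITrials(generateMITrials(10, cfg))
  model <- fitCICSP(trials, m = 2, k = 1)
  expect_s4_class(model, "CICSPModel")
  expect_equal(2 * model@m + model@k, 5)   # C = 10, m = 2, k = 1
  expect_identical(model@classes, c("left", "right"))
  expect_equal(sum(colSums(model@pcaLoading^2)), 1, tolerance = 1e-12)
  expect_gte(trainAccuracy(model), 0.9)

  # filters diagonalize the composite covariance; after CAR the data span
  # only 9 of 10 dimensions, so one diagonal entry (the common-average
  # direction, eigenvalue 1/2) carries no variance
  covs <- classCovariances(
    TrialSet(lapply(trialData(trials),
                    function(x) x[match(miChannels(), channelNames(trials)), ]),
             trialLabels(trials), miChannels(), samplingRate(trials)))
  W <- spatialFilters(model)
  D <- W %*% (covs[[1]] + covs[[2]]) %*% t(W)
  expect_lt(max(abs(D - diag(diag(D)))), 1e-6)
  expect_equal(sum(abs(diag(D) - 1) < 1e-6), 9)
  expect_equal(sum(abs(diag(D)) < 1e-6), 1)

  expect_error(fitCICSP(trials, m = 2, k = 7), "intermediate")
})

test_that("online prediction uses sub-windows and stays amplitude invariant", {
  cfg <- fastConfig(seed = 95)
  trials <- preprocessMITrials(generateMITrials(12, cfg))
  model <- fitCICSP(trials)

  test <- preprocessMITrials(generateMITrials(10, fastConfig(seed = 950)))
  wins <- lapply(seq_len(nTrials(test)), function(i)
    new("EpochWindow", data = trialData(test)[[i]],
        labels = channelNames(test), fs = samplingRate(test), onset_s = 0))
  online <- vapply(wins, predictMIOnline, "", model = model)
  batch <- predictCICSP(model, test)

  # strong ERD windows decode to the imagined side
  expect_gte(mean(online == trialLabels(test)), 0.9)
  # batch and online paths agree on most high-SNR windows
  expect_gte(mean(online == batch), 0.85)

  # amplitude scaling leaves the prediction unchanged
  w <- wins[[1]]
  ws <- new("EpochWindow", data = 10 * eegData(w), labels = channelNames(w),
            fs = samplingRate(w), onset_s = 0)
  expect_identical(predictMIOnline(ws, model), predictMIOnline(w, model))

  short <- new("EpochWindow", data = eegData(w)[, 1:100],
               labels = channelNames(w), fs = samplingRate(w), onset_s = 0)
  expect_error(predictMIOnline(short, model), "1.5 s")
})

test_that("accuracy is non-decreasing in ERD depth", {
  accAtDepth <- function(depth) {
    cfg <- fastConfig(seed = 96, erdDepth = depth)
    model <- fitCICSP(preprocessMITrials(generateMITrials(15, cfg)))
    testCfg <- fastConfig(seed = 960, erdDepth = depth)
    test <- preprocessMITrials(generateMITrials(15, testCfg))
    mean(predictCICSP(model, test) == trialLabels(test))
  }
  accs <- vapply(c(0, 0.3, 0.6, 0.9), accAtDepth, 0)
  expect_true(all(diff(accs) >= -0.02))
  expect_gte(accs[4], 0.9)
})

test_that("keeping intermediate-filter information does not hurt accuracy", {
  # class covariances whose discriminative structure extends into the
  # middle eigenvectors, so the intermediate filters carry information
  runPair <- function(seed) {
    set.seed(seed)
    vA <- c(3.0, 2.5, 2.0, 1.8, 1, 1, 1, 1)
    vB <- rev(vA)
    gen <- function(v, n) lapply(seq_len(n), function(i)
      diag(sqrt(v)) %*% matrix(rnorm(8 * 200), 8))
    chans <- paste0("ch", 1:8)
    mk <- function(n) TrialSet(c(gen(vA, n), gen(vB, n)),
                               rep(c("left", "right"), each = n), chans, 250)
    train <- mk(25); test <- mk(15)
    acc <- function(k) {
      m <- fitCICSP(train, m = 2, k = k, channels = chans)
      mean(predictCICSP(m, test) == trialLabels(test))
    }
    c(cicsp = acc(1), csp = acc(0))
  }
  res <- vapply(1:6, runPair, numeric(2))
  expect_gte(mean(res["cicsp", ]), mean(res["csp", ]) - 0.01)
})

test_that("decoder models round-trip through serialization", {
  cfg <- fastConfig(seed = 97)
  model <- fitCICSP(preprocessMITrials(generateMITrials(6, cfg)))
  path <- tempfile(fileext = ".rds")
  writeDecoderModel(model, path)
  back <- readDecoderModel(path)
  expect_equal(spatialFilters(back), spatialFilters(model))
  test <- preprocessMITrials(generateMITrials(4, fastConfig(seed = 970)))
  expect_identical(predictCICSP(back, test), predictCICSP(model, test))
  saveRDS(list(a = 1), path)
  expect_error(readDecoderModel(path), "not a decoder model")
})
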