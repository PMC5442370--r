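# The two-step between-subject classifier.

test_that("weighted channel averaging is the stated convex combination", {
  feat <- array(0, c(2, 2, 3))
  feat[, 1, ] <- 1
  feat[, 2, ] <- 0
  expect_equal(weightedChannelAverage(feat, c(0.75, 0.25)),
               matrix(0.75, 2, 3))
  expect_equal(weightedChannelAverage(feat, c(1, 0)), matrix(1, 2, 3))
  # equal weights give the plain mean
  set.seed(1)
  feat2 <- array(rnorm(2 * 4 * 3), c(2, 4, 3))
  expect_equal(weightedChannelAverage(feat2, rep(0.5, 4)),
               apply(feat2, c(1, 3), mean))
  expect_error(weightedChannelAverage(feat, c(0, 0)), "zero")
})

test_that("the inner channel loop finds the informative channel", {
  se <- toyFeatureSE(nSubjects = 10, nGroups = 4, nBins = 6, delta = 3,
                     signalGroup = 2, sd = 0.3, seed = 2)
  feat <- somnidec:::featuresArray(se)
  cd <- SummarizedExperiment::colData(se)
  y <- ifelse(cd$condition == "face", 1, -1)
  subj <- match(cd$subjectId, unique(cd$subjectId))
  inner <- innerChannelLoop(feat, y, subj)
  expect_equal(dim(inner$meanAbsW), c(4, 6))
  expect_gte(inner$accuracy[2], 0.95)
  expect_equal(which.max(inner$accuracy), 2L)
  # channels without information stay near chance
  expect_true(all(abs(inner$accuracy[-2] - 0.5) < 0.35))
  # identical features across conditions: all channels at chance +/- noise
  se0 <- toyFeatureSE(nSubjects = 10, nGroups = 4, nBins = 6, delta = 0,
                      seed = 3)
  inner0 <- innerChannelLoop(somnidec:::featuresArray(se0), y, subj)
  expect_true(all(abs(inner0$accuracy - 0.5) <= 0.35))
  expect_error(innerChannelLoop(feat, rep(1, length(y)), subj), "class")
})

test_that("the main classifier separates trivially separable data", {
  X <- rbind(matrix(rep(c(1, 0, 0), 5), 5, byrow = TRUE),
             matrix(rep(c(-1, 0, 0), 5), 5, byrow = TRUE))
  y <- c(rep(1, 5), rep(-1, 5))
  model <- trainMainClassifier(X, y)
  pr <- predictMain(model, X)
  expect_equal(mean(pr$predicted == y), 1)
  expect_true(all(pr$probFace > 0 & pr$probFace < 1))
  # probabilities are monotone in the decision value
  ord <- order(pr$decision)
  expect_true(all(diff(pr$probFace[ord]) >= 0))
  # label swap negates decision values (linear antisymmetry)
  m2 <- trainMainClassifier(X, -y)
  pr2 <- predictMain(m2, X)
  expect_equal(pr2$decision, -pr$decision, tolerance = 1e-9)
  expect_error(trainMainClassifier(X, rep(1, 10)), "classes")
})

test_that("cross-validated decoding recovers signal and stays at chance on null", {
  seSig <- toyFeatureSE(nSubjects = 12, nGroups = 4, nBins = 6, delta = 3,
                        signalGroup = 2, sd = 0.3, seed = 4)
  res <- crossValidatedDecode(seSig, reps = 10, folds = 5, seed = 1)
  expect_gt(validationAccuracy(res), 0.8)
  expect_equal(dim(innerWeights(res)), c(4, 6))
  expect_length(res@outerWeights, 6)
  expect_length(probEstimates(res), 24)
  expect_true(all(probEstimates(res) >= 0 & probEstimates(res) <= 1))
  # generalization: training close to validation for strong signal
  expect_lt(trainingAccuracy(res) - validationAccuracy(res), 0.15)
  # determinism
  res2 <- crossValidatedDecode(seSig, reps = 10, folds = 5, seed = 1)
  expect_equal(validationAccuracy(res2), validationAccuracy(res))
  expect_equal(probEstimates(res2), probEstimates(res))
  # null features: accuracy within the chance band
  se0 <- toyFeatureSE(nSubjects = 12, nGroups = 4, nBins = 6, delta = 0,
                      seed = 5)
  res0 <- crossValidatedDecode(se0, reps = 10, folds = 5, seed = 1)
  expect_gt(validationAccuracy(res0), 0.3)
  expect_lt(validationAccuracy(res0), 0.7)
  expect_error(crossValidatedDecode(seSig, folds = 40), "folds")
})

test_that("probability estimates agree in direction with accuracy", {
  for (seed in 1:3) {
    se <- toyFeatureSE(nSubjects = 10, nGroups = 2, nBins = 4,
                       delta = ifelse(seed == 1, 2, 0.3), sd = 0.5,
                       seed = seed)
    res <- crossValidatedDecode(se, reps = 8, folds = 5, seed = seed)
    expect_equal(mean(probEstimates(res)) >= 0.5,
                 validationAccuracy(res) >= 0.5,
                 label = paste("prob/accuracy consistency, seed", seed))
  }
})

test_that("no validation datum influences the trained model (leakage)", {
  se <- toyFeatureSE(nSubjects = 10, nGroups = 3, nBins = 4, delta = 1,
                     seed = 6)
  feat <- somnidec:::featuresArray(se)
  cd <- SummarizedExperiment::colData(se)
  y <- ifelse(cd$condition == "face", 1, -1)
  subj <- match(cd$subjectId, unique(cd$subjectId))
  trIdx <- which(subj <= 8)
  teIdx <- which(subj > 8)
  fitOn <- function(yy) {
    inner <- innerChannelLoop(feat[trIdx, , ], yy[trIdx],
                              subj[trIdx])
    Xtr <- weightedChannelAverage(feat[trIdx, , ], inner$accuracy)
    trainMainClassifier(Xtr, yy[trIdx])
  }
  yShuf <- y
  yShuf[teIdx] <- -yShuf[teIdx]  # corrupt only validation labels
  expect_identical(fitOn(y), fitOn(yShuf))
})

test_that("both nights of a subject always share a fold", {
  # observable consequence: with features identical for both nights of
  # each subject and labels opposite, any subject-level split keeps the
  # pair together, so per-subject probability estimates of the two
  # nights sum to ~1 (same model scores both nights)
  set.seed(8)
  nS <- 10
  X <- matrix(rnorm(12 * nS), 12)
  X2 <- X[, rep(seq_len(nS), each = 2)]
  subj <- rep(sprintf("s%02d", seq_len(nS)), each = 2)
  cond <- rep(c("face", "house"), nS)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = X2),
    colData = S4Vectors::DataFrame(subjectId = subj, night = rep(1:2, nS),
                                   condition = cond, nTrials = 50L,
                                   row.names = paste0(subj, "_n", rep(1:2, nS))))
  S4Vectors::metadata(se) <- list(stage = "S2", segment = 1L,
                                  nGroups = 3L, nBins = 4L)
  res <- crossValidatedDecode(se, reps = 6, folds = 5, seed = 2)
  p <- probEstimates(res)
  pairSum <- p[seq(1, 2 * nS, 2)] + p[seq(2, 2 * nS, 2)]
  expect_equal(unname(pairSum), rep(1, nS), tolerance = 1e-6)
})

test_that("band maps partition the 60 bins and locate a seeded band", {
  bands <- frequencyBands()
  f <- seq(0.5, 30, 0.5)
  idx <- lapply(bands, somnidec:::bandBins, freqs = f)
  expect_equal(vapply(idx, length, 0L),
               c(delta = 7L, theta = 8L, alpha = 6L, spindle = 10L,
                 beta = 29L))
  expect_equal(sort(unname(unlist(idx))), seq_len(60))  # no bin in two bands
  # weight maps: all-equal weights give flat profile and topography
  res <- new("DecodingResult", validationAccuracy = 0.5,
             trainingAccuracy = 0.5, probEstimates = c(a = 0.5),
             innerWeights = matrix(1, 32, 60), outerWeights = rep(1, 60),
             channelWeights = rep(0.5, 32), cell = list(stage = "S2",
                                                        segment = 1L),
             nSubjects = 12L, reps = 1L, folds = 5L, cost = 1,
             seed = 1L, fingerprint = "x")
  maps <- featureWeightMaps(res)
  expect_equal(unname(maps$frequencyProfile), rep(1, 60))
  expect_true(all(maps$topography == 1))
  expect_error(featureWeightMaps(res, list(bad = c(0.1, 5))), "band")
})

test_that("the two-step procedure matches the brute-force oracle", {
  # 6 subjects x 2 nights, 2 channels x 3 bins, fixed fold assignment
  se <- toyFeatureSE(nSubjects = 6, nGroups = 2, nBins = 3, delta = 1.5,
                     signalGroup = 1, sd = 0.4, seed = 9)
  feat <- somnidec:::featuresArray(se)
  cd <- SummarizedExperiment::colData(se)
  y <- ifelse(cd$condition == "face", 1, -1)
  subjIdx <- match(cd$subjectId, unique(cd$subjectId))
  foldOf <- c(1, 1, 2, 2, 3, 3)  # 3 folds of 2 subjects
  oracle <- oracleTwoStep(feat, y, subjIdx, foldOf)
  # package path with the same explicit folds
  correct <- 0; total <- 0
  wchAll <- NULL
  for (f in 1:3) {
    testSubj <- which(foldOf == f)
    trIdx <- which(!(subjIdx %in% testSubj))
    teIdx <- which(subjIdx %in% testSubj)
    inner <- innerChannelLoop(feat[trIdx, , ], y[trIdx],
                              match(subjIdx[trIdx], unique(subjIdx[trIdx])))
    Xtr <- weightedChannelAverage(feat[trIdx, , ], inner$accuracy)
    Xte <- weightedChannelAverage(feat[teIdx, , ], inner$accuracy)
    model <- trainMainClassifier(Xtr, y[trIdx])
    pr <- predictMain(model, Xte)
    correct <- correct + sum(pr$predicted == y[teIdx])
    total <- total + length(teIdx)
    wchAll <- rbind(wchAll, inner$accuracy)
  }
  expect_equal(correct / total, oracle$accuracy, tolerance = 5e-4)
  expect_equal(wchAll[3, ], oracle$channelWeights, tolerance = 5e-4)
})
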