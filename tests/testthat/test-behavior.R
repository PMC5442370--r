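# Recognition-memory scoring and the reprocessing-behaviour statistics.

test_that("d-prime has the stated closed forms and symmetries", {
  # equal hit and false-alarm rates give zero
  expect_equal(dprime(50, 100, 25, 50), 0)
  # worked value via the inverse-normal oracle after correction
  expect_equal(dprime(84, 100, 16, 100),
               qnorm(84.5 / 101) - qnorm(16.5 / 101))
  # perfect scores stay finite through the log-linear correction
  expect_true(is.finite(dprime(100, 100, 0, 50)))
  # antisymmetry: swapping hit and false-alarm rates negates d-prime
  expect_equal(dprime(80, 100, 10, 50), -dprime(20, 100, 40, 50))
  expect_error(dprime(5, 0, 1, 10), "nOld")
  expect_error(dprime(105, 100, 1, 50), "range")
})

test_that("reprocessing strength is the mean true-class probability", {
  res <- new("DecodingResult", validationAccuracy = 1, trainingAccuracy = 1,
             probEstimates = c(s01_n1 = 1, s01_n2 = 1, s02_n1 = 0.5,
                               s02_n2 = 0.5),
             innerWeights = matrix(0, 2, 3), outerWeights = rep(0, 3),
             channelWeights = c(0.5, 0.5), cell = list(stage = "SWS",
                                                       segment = 2L),
             nSubjects = 2L, reps = 1L, folds = 2L, cost = 1, seed = 1L,
             fingerprint = "x")
  expect_equal(unname(reprocessingStrength(res)["s01_n1"]), 1)
  bySubj <- reprocessingStrength(res, bySubject = TRUE)
  expect_equal(unname(bySubj[["s02"]]), 0.5)
  # strength grows with signature amplitude (parameter recovery)
  strengths <- vapply(c(0, 0.15, 0.45), function(a) {
    cfg <- simConfig(nSubjects = 12, signatureAmplitude = a,
                     amplitudeGainSd = 0, trialStride = 4L, seed = 77)
    coh <- simulateCohort(cfg, level = "cells")
    se <- buildCellFeatures(coh, "SWS", 2, minSubjects = 11)
    mean(probEstimates(crossValidatedDecode(se, reps = 5, folds = 5,
                                            seed = 1)))
  }, 0)
  expect_true(all(diff(strengths) > 0))
})

test_that("Spearman correlation handles monotone, reversed and null data", {
  x <- c(1, 4, 9, 16, 25)
  expect_equal(spearmanRho(x, sqrt(x))$rho, 1)
  expect_equal(spearmanRho(1:5 + 0, 5:1 + 0)$rho, -1)
  r <- spearmanRho(1:5, c(2, 1, 4, 3, 5))
  expect_equal(r$rho, cor(1:5, c(2, 1, 4, 3, 5), method = "spearman"))
  # null distribution is centred: mean rho over replicates near zero
  set.seed(10)
  rhos <- replicate(400, spearmanRho(rnorm(64), rnorm(64))$rho)
  expect_lt(abs(mean(rhos)), 0.05)
  expect_error(spearmanRho(rep(1, 6), 1:6), "constant")
  expect_error(spearmanRho(1:4, 1:4), "at least 5")
})

test_that("partial Spearman removes a shared component", {
  set.seed(11)
  z <- rnorm(200)
  x <- rnorm(200)
  y <- rnorm(200)
  # independent control barely changes the correlation
  p0 <- partialSpearman(x, x + y, z)
  r0 <- spearmanRho(x, x + y)
  expect_equal(p0$rho, r0$rho, tolerance = 0.05)
  # y ~= z: controlling for z removes the shared part entirely
  p1 <- partialSpearman(x + z, z + 0.01 * rnorm(200), z)
  expect_lt(abs(p1$rho), 0.15)
  # exact rank collinearity with the control is rejected
  expect_error(partialSpearman(x + z, z, z), "collinear")
  # symmetry in x and y
  expect_equal(partialSpearman(x, y, z)$rho, partialSpearman(y, x, z)$rho)
})

test_that("the regression decomposes variance by squared semipartials", {
  set.seed(12)
  x <- rnorm(40)
  fit1 <- suppressWarnings(reprocessingRegression(data.frame(S = x), x))
  expect_equal(fit1$coefficients$beta, 1)
  expect_equal(fit1$coefficients$sr2, 1, tolerance = 1e-9)
  # orthogonal predictors: betas equal the marginal standardized slopes
  n <- 64
  a <- rep(c(1, -1), n / 2)
  b <- rep(c(1, 1, -1, -1), n / 4)
  y <- 0.6 * a + 0.3 * b + rnorm(n, 0, 0.4)
  fit2 <- reprocessingRegression(data.frame(A = a, B = b), y)
  m1 <- coef(lm(scale(y) ~ scale(a)))[2]
  m2 <- coef(lm(scale(y) ~ scale(b)))[2]
  expect_equal(fit2$coefficients$beta, unname(c(m1, m2)), tolerance = 1e-9)
  expect_error(reprocessingRegression(data.frame(A = a, B = a), y),
               "collinear")
  expect_error(reprocessingRegression(data.frame(A = 1:5), 1:5), "10")
})

test_that("the slope-interaction test separates unequal slopes", {
  set.seed(13)
  n <- 64
  # identical slopes: the interaction p-value behaves like a null test
  ps <- replicate(60, {
    s1 <- rnorm(n); s2 <- rnorm(n)
    y <- 0.5 * s1 + 0.5 * s2 + rnorm(n, 0, 0.5)
    slopeInteractionTest(s1, s2, y)$pInteraction
  })
  expect_gt(mean(ps > 0.05), 0.85)
  # opposite slopes at low noise: decisively significant
  s1 <- rnorm(n); s2 <- rnorm(n)
  y2 <- 0.8 * s1 - 0.8 * s2 + rnorm(n, 0, 0.1)
  expect_lt(slopeInteractionTest(s1, s2, y2)$pInteraction, 0.01)
  # balanced homoskedastic case: the interaction coefficient equals the
  # difference of the two separate OLS slopes
  it <- slopeInteractionTest(s1, s2, y2)
  sep <- coef(lm(y2 ~ s2))[2] - coef(lm(y2 ~ s1))[2]
  expect_equal(it$estimate, unname(sep), tolerance = 1e-9)
})

test_that("leverage filtering follows the hat-matrix closed form", {
  x <- seq(-3, 3, length.out = 13)
  y <- x + rnorm(13, 0, 0.1)
  h <- hatvalues(lm(y ~ x))
  # closed form h_i = 1/n + (x_i - xbar)^2 / sum((x - xbar)^2)
  expect_equal(unname(h), 1 / 13 + (x - mean(x))^2 / sum((x - mean(x))^2))
  # trace of the hat matrix equals the number of parameters
  expect_equal(sum(h), 2)
  # extreme-x points have the largest leverage and are removed first
  keep <- leverageFilter(x, y, k = 2)
  expect_false(1 %in% keep)
  expect_false(13 %in% keep)
  expect_length(keep, 11)
  expect_equal(leverageFilter(x, y, k = 0), 1:13)
  expect_error(leverageFilter(x, y, k = 13), "k must")
})
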