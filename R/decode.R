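# The two-step between-subject classifier.
#
# Step 1 (inner loop): one linear SVM per channel group, trained on all
# but one training subject and evaluated on the held-out subject's two
# nights (leave-one-subject-out over the training set).  The mean
# held-out accuracy of each channel becomes its weight.
# Step 2 (outer): the 32 channels are averaged with those weights into a
# single 60-bin vector per night; the main linear SVM is trained on the
# weighted training vectors and evaluated on the held-out validation
# subjects.  The whole procedure is repeated over many random subject-
# level 5-fold partitions; both nights of a subject always share a fold.

labelSign <- function(condition) ifelse(condition == "face", 1, -1)

#' Per-channel leave-one-subject-out accuracies (channel weights)
#'
#' @param feat nights x channels x bins feature array (training subjects)
#' @param y +1/-1 labels per night
#' @param subjectIdx integer subject index per night (paired nights share
#'   an index and are always held out together)
#' @param cost SVM cost C
#' @return list(accuracy = per-channel fraction in [0, 1],
#'   meanAbsW = channels x bins mean absolute SVM weights)
#' @export
innerChannelLoop <- function(feat, y, subjectIdx, cost = 1) {
  d <- dim(feat)
  if (length(unique(subjectIdx)) < 3L)
    stop("need at least 3 training subjects for the inner loop")
  if (length(unique(sign(y))) < 2L)
    stop("a class is absent from the training set")
  res <- .cppLosoChannels(as.numeric(feat), as.integer(d),
                          as.integer(subjectIdx) - 1L, as.numeric(y),
                          C = cost)
  list(accuracy = res$accuracy, meanAbsW = res$meanAbsW)
}

#' Accuracy-weighted average of the channel groups
#'
#' \code{out[n, f] = sum_c w_c feat[n, c, f] / sum_c w_c}
#'
#' @param feat nights x channels x bins array (or channels x bins matrix
#'   for a single night)
#' @param weights per-channel weights (not all zero)
#' @return nights x bins matrix (or a bin vector for a single night)
#' @export
weightedChannelAverage <- function(feat, weights) {
  if (all(weights == 0)) stop("all channel weights are zero")
  if (is.matrix(feat)) {
    return(as.numeric(crossprod(weights, feat)) / sum(weights))
  }
  d <- dim(feat)
  out <- matrix(0, d[1], d[3])
  for (c in seq_len(d[2])) out <- out + weights[c] * feat[, c, ]
  out / sum(weights)
}

# Platt-style logistic calibration P(y=+1 | dec) = 1/(1+exp(A*dec+B)),
# fitted by Newton iterations on the training decision values with the
# usual smoothed targets so separable data keep a finite slope.
plattFit <- function(dec, y, maxIter = 100L) {
  n1 <- sum(y > 0)
  n0 <- sum(y <= 0)
  t1 <- (n1 + 1) / (n1 + 2)
  t0 <- 1 / (n0 + 2)
  tt <- ifelse(y > 0, t1, t0)
  A <- 0
  B <- log((n0 + 1) / (n1 + 1))
  for (it in seq_len(maxIter)) {
    fApB <- A * dec + B
    p <- ifelse(fApB >= 0, exp(-fApB) / (1 + exp(-fApB)),
                1 / (1 + exp(fApB)))
    # gradient of the calibration negative log-likelihood
    g1 <- sum((tt - p) * dec)
    g2 <- sum(tt - p)
    if (max(abs(g1), abs(g2)) < 1e-7) break
    w <- p * (1 - p)
    h11 <- sum(w * dec * dec) + 1e-12
    h22 <- sum(w) + 1e-12
    h21 <- sum(w * dec)
    det <- h11 * h22 - h21^2
    A <- A - (h22 * g1 - h21 * g2) / det
    B <- B - (-h21 * g1 + h11 * g2) / det
  }
  c(A = A, B = B)
}

#' Train the main classifier on weighted channel averages
#'
#' Fits a linear soft-margin SVM (cost C) on the 60-bin weighted-average
#' vectors and calibrates probability estimates by a Platt-style logistic
#' fit on the training decision values only.
#'
#' @param X nights x bins matrix of weighted averages (training set)
#' @param y +1/-1 labels
#' @param cost SVM cost C (default 1)
#' @return list(w, b, A, B) model; see \code{\link{predictMain}}
#' @export
trainMainClassifier <- function(X, y, cost = 1) {
  if (length(unique(sign(y))) < 2L) stop("both classes must be present")
  fit <- .cppSvmFit(X, as.numeric(y), C = cost)
  dec <- as.numeric(X %*% fit$w) + fit$b
  ab <- plattFit(dec, y)
  list(w = fit$w, b = fit$b, A = ab[["A"]], B = ab[["B"]])
}

#' Predict with the main classifier
#'
#' @param model from \code{\link{trainMainClassifier}}
#' @param X nights x bins matrix
#' @return data.frame(decision, predicted = +1/-1, probFace) where
#'   \code{probFace} is the calibrated probability of the positive (face)
#'   class; a decision value of exactly zero is assigned to face
#' @export
predictMain <- function(model, X) {
  if (is.vector(X)) X <- matrix(X, 1L)
  dec <- as.numeric(X %*% model$w) + model$b
  fApB <- model$A * dec + model$B
  p <- ifelse(fApB >= 0, exp(-fApB) / (1 + exp(-fApB)), 1 / (1 + exp(fApB)))
  data.frame(decision = dec, predicted = ifelse(dec >= 0, 1, -1),
             probFace = p)
}

# subject-level fold assignment; fold sizes differ by at most one
assignFolds <- function(subjects, k) {
  n <- length(subjects)
  sizes <- rep(floor(n / k), k)
  extra <- n - sum(sizes)
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  rep(seq_len(k), times = sizes)[order(order(runif(n)))]
}

# fast prediction path used in the cross-validation loops
predictDecision <- function(model, X) as.numeric(X %*% model$w) + model$b

# Plain-array core of the repeated k-fold two-step procedure.  Keeps the
# permutation engine free of container overhead; crossValidatedDecode
# wraps the result into the S4 class.
decodeCore <- function(feat, y, subjIdx, reps, folds, cost, seed,
                       nightIds = NULL) {
  subjects <- unique(subjIdx)
  nS <- length(subjects)
  if (nS < folds) stop("fewer subjects than folds")
  d <- dim(feat)
  nN <- d[1]
  probSum <- numeric(nN)
  probCnt <- numeric(nN)
  innerW <- matrix(0, d[2], d[3])
  outerW <- numeric(d[3])
  chW <- numeric(d[2])
  nAgg <- 0L
  valAcc <- numeric(reps)
  trnAcc <- numeric(reps)
  withSeed(splitSeed(seed, 1L), {
    for (rp in seq_len(reps)) {
      fold <- assignFolds(subjects, folds)
      vCorr <- 0; vTot <- 0; tCorr <- 0; tTot <- 0
      for (f in seq_len(folds)) {
        testSubj <- subjects[fold == f]
        te <- subjIdx %in% testSubj
        trIdx <- which(!te)
        teIdx <- which(te)
        if (!length(teIdx)) next
        res <- .cppLosoChannels(as.numeric(feat[trIdx, , , drop = FALSE]),
                                as.integer(c(length(trIdx), d[2], d[3])),
                                match(subjIdx[trIdx],
                                      unique(subjIdx[trIdx])) - 1L,
                                as.numeric(y[trIdx]), C = cost)
        wch <- res$accuracy
        if (all(wch == 0)) wch <- rep(1, length(wch))
        Xtr <- weightedChannelAverage(feat[trIdx, , , drop = FALSE], wch)
        Xte <- weightedChannelAverage(feat[teIdx, , , drop = FALSE], wch)
        model <- trainMainClassifier(Xtr, y[trIdx], cost = cost)
        decTe <- predictDecision(model, Xte)
        decTr <- predictDecision(model, Xtr)
        predTe <- ifelse(decTe >= 0, 1, -1)
        vCorr <- vCorr + sum(predTe == y[teIdx])
        vTot <- vTot + length(teIdx)
        tCorr <- tCorr + sum(ifelse(decTr >= 0, 1, -1) == y[trIdx])
        tTot <- tTot + length(trIdx)
        fApB <- model$A * decTe + model$B
        pFace <- ifelse(fApB >= 0, exp(-fApB) / (1 + exp(-fApB)),
                        1 / (1 + exp(fApB)))
        probSum[teIdx] <- probSum[teIdx] +
          ifelse(y[teIdx] > 0, pFace, 1 - pFace)
        probCnt[teIdx] <- probCnt[teIdx] + 1
        innerW <- innerW + res$meanAbsW
        outerW <- outerW + abs(model$w)
        chW <- chW + wch
        nAgg <- nAgg + 1L
      }
      valAcc[rp] <- vCorr / vTot
      trnAcc[rp] <- tCorr / tTot
    }
  })
  list(validationAccuracy = mean(valAcc), trainingAccuracy = mean(trnAcc),
       probEstimates = setNames(probSum / pmax(probCnt, 1), nightIds),
       innerWeights = innerW / nAgg, outerWeights = outerW / nAgg,
       channelWeights = chW / nAgg, nSubjects = nS)
}

#' Cross-validated two-step decoding of one analysis cell
#'
#' Runs \code{reps} repetitions of a subject-level k-fold procedure.  In
#' every fold, channel weights are established by the inner
#' leave-one-subject-out loop on the training folds only, the main SVM is
#' trained on the weighted training vectors, and accuracy plus calibrated
#' probability estimates are computed on the held-out fold.  Nothing from
#' a validation fold ever influences weights, classifier or calibration.
#'
#' @param se a cell's SummarizedExperiment from
#'   \code{\link{buildCellFeatures}}
#' @param reps repetitions of the k-fold procedure (default 280, the
#'   full-scale setting; reduce for exploratory runs)
#' @param folds number of folds (default 5)
#' @param cost SVM cost C (default 1)
#' @param seed RNG seed; fixed seed gives an identical result
#' @return A \linkS4class{DecodingResult}.
#' @export
crossValidatedDecode <- function(se, reps = 280, folds = 5, cost = 1,
                                 seed = 1L) {
  feat <- featuresArray(se)
  cd <- colData(se)
  subjIdx <- match(cd$subjectId, unique(cd$subjectId))
  y <- labelSign(cd$condition)
  core <- decodeCore(feat, y, subjIdx, reps = reps, folds = folds,
                     cost = cost, seed = seed, nightIds = rownames(cd))
  fp <- fingerprintOf(list(reps = reps, folds = folds, cost = cost,
                           cell = metadata(se)[c("stage", "segment")],
                           nights = rownames(cd)))
  new("DecodingResult",
      validationAccuracy = core$validationAccuracy,
      trainingAccuracy = core$trainingAccuracy,
      probEstimates = core$probEstimates,
      innerWeights = core$innerWeights, outerWeights = core$outerWeights,
      channelWeights = core$channelWeights,
      cell = list(stage = metadata(se)$stage,
                  segment = metadata(se)$segment),
      nSubjects = core$nSubjects, reps = as.integer(reps),
      folds = as.integer(folds), cost = cost, seed = as.integer(seed),
      fingerprint = fp)
}

#' Band-averaged weight topographies and frequency profile
#'
#' Summarizes a decoding result's inner 32 x 60 weight matrix: the
#' frequency profile is the mean absolute weight over channels per bin;
#' the topography gives, per channel, the mean absolute weight within
#' each canonical band (delta, theta, alpha, spindle, beta).
#'
#' @param result a \linkS4class{DecodingResult}
#' @param bands named list of band edges (default
#'   \code{\link{frequencyBands}}); bands must lie within 0.5--30 Hz
#' @return list(frequencyProfile = per-bin numeric,
#'   topography = channels x bands matrix)
#' @export
featureWeightMaps <- function(result, bands = frequencyBands()) {
  W <- abs(innerWeights(result))
  freqs <- analysisFreqs()[seq_len(ncol(W))]
  for (b in bands)
    if (b[1] < 0.5 - 1e-9 || b[2] > 30 + 1e-9)
      stop("band outside the 0.5-30 Hz analysis range")
  topo <- sapply(bands, function(b) rowMeans(W[, bandBins(b, freqs),
                                               drop = FALSE]))
  list(frequencyProfile = colMeans(W), topography = topo)
}
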