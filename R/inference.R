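# Permutation inference and the sliding-window time course.
#
# The permutation group is the per-subject swap of the two night labels:
# each subject's nights are independently relabelled face/house or
# house/face with probability 1/2, which preserves the paired structure
# and removes all condition information while keeping every other
# dependency in the data intact.

#' Permute condition labels per subject
#'
#' Independently for every subject, swaps the labels of the two nights
#' with probability 0.5.  The pairing structure (one face and one house
#' night per subject) is preserved by construction.
#'
#' @param se a cell's SummarizedExperiment
#' @param seed RNG seed
#' @return the SummarizedExperiment with permuted \code{condition} labels
#' @export
permuteLabels <- function(se, seed = 1L) {
  cd <- colData(se)
  subjects <- unique(cd$subjectId)
  if (!all(table(cd$subjectId) == 2L))
    stop("permutation requires paired nights for every subject")
  swap <- withSeed(splitSeed(seed, 7L),
                   runif(length(subjects)) < 0.5)
  names(swap) <- subjects
  flip <- swap[cd$subjectId]
  cond <- cd$condition
  cond[flip] <- ifelse(cond[flip] == "face", "house", "face")
  colData(se)$condition <- cond
  se
}

#' Label-permutation significance test for a decoding accuracy
#'
#' Re-runs the complete two-step decoding procedure (including the inner
#' channel loop) on \code{nPerm} randomly relabelled copies of the data,
#' using the identical decoding configuration as the observed run.  The
#' p-value is the fraction of null runs with accuracy greater than or
#' equal to the observed one; if no null run reaches it, p is reported as
#' a strict bound p < 1/nPerm.
#'
#' @param se a cell's SummarizedExperiment
#' @param nPerm number of permutations (default 1001, the full-scale
#'   setting; the attainable precision floor is 1/nPerm)
#' @param reps decoding repetitions per permutation and for the observed
#'   statistic (default 5; the observed statistic is computed at the same
#'   reduced setting so observed and null are exchangeable)
#' @param folds,cost decoding settings
#' @param seed RNG seed (fully determines the null distribution)
#' @param observed optional precomputed \linkS4class{DecodingResult}
#'   matching \code{reps}/\code{folds}/\code{cost}; recomputed when NULL
#' @return A \linkS4class{NullDistribution}.
#' @export
permutationTest <- function(se, nPerm = 1001, reps = 5, folds = 5,
                            cost = 1, seed = 1L, observed = NULL) {
  if (nPerm < 19)
    warning("fewer than 19 permutations cannot reach alpha = 0.05")
  if (is.null(observed))
    observed <- crossValidatedDecode(se, reps = reps, folds = folds,
                                     cost = cost, seed = splitSeed(seed, 0L))
  obs <- validationAccuracy(observed)
  # the null runs re-execute the identical two-step pipeline (inner loop
  # included) on per-subject label swaps, via the plain-array core
  cd <- colData(se)
  if (!all(table(cd$subjectId) == 2L))
    stop("permutation requires paired nights for every subject")
  feat <- featuresArray(se)
  subjIdx <- match(cd$subjectId, unique(cd$subjectId))
  y <- ifelse(cd$condition == "face", 1, -1)
  nSub <- max(subjIdx)
  nullAcc <- numeric(nPerm)
  for (i in seq_len(nPerm)) {
    swap <- withSeed(splitSeed(splitSeed(seed, 10L, i), 7L),
                     runif(nSub) < 0.5)
    yP <- ifelse(swap[subjIdx], -y, y)
    nullAcc[i] <- decodeCore(feat, yP, subjIdx, reps = reps,
                             folds = folds, cost = cost,
                             seed = splitSeed(seed, 11L, i)
                             )$validationAccuracy
  }
  cnt <- sum(nullAcc >= obs - 1e-12)
  bound <- cnt == 0L
  p <- if (bound) 1 / nPerm else cnt / nPerm
  new("NullDistribution", accuracies = nullAcc, observed = obs,
      pValue = p, bound = bound, nPerm = as.integer(nPerm),
      fingerprint = observed@fingerprint)
}

#' Holm step-down adjustment of a p-value family
#'
#' @param p numeric vector of p-values in [0, 1] (the family is all
#'   stage x segment cells tested in one run)
#' @return adjusted p-values (monotone, familywise error controlling)
#' @export
holmCorrect <- function(p) {
  if (!length(p)) stop("empty p-value family")
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "holm")
}

#' Sliding-window time course of decoding accuracy
#'
#' Moves a window of \code{width} minutes in steps of \code{step} minutes
#' across the night.  Within each window, every subject-night's trials of
#' the requested stage whose onsets fall inside the window are averaged,
#' normalized and sharpened exactly as in the main analysis, and the
#' two-step classifier is run on the resulting features.  Windows in
#' which fewer than \code{minSubjects} subjects reach \code{minTrials}
#' clean trials (with both nights) are reported as missing, not zero.
#'
#' @param cohort a trials-level \linkS4class{SleepCohort}
#' @param stage analysis stage ("S2", "SWS", "REM")
#' @param width window width, minutes (default 22.5)
#' @param step step between window onsets, minutes (default 4.5)
#' @param minTrials per-window per-night inclusion threshold (default 8,
#'   a documented scaled-down analogue of the 40-trial cell criterion)
#' @param minSubjects per-window subject minimum (default 11)
#' @param reps,folds,cost,seed decoding settings (reduced reps by default)
#' @param swsMode "s3s4" or "s4"
#' @return data.frame(centreMin, accuracy, nSubjects); accuracy is NA for
#'   windows failing inclusion
#' @export
slidingWindowTimecourse <- function(cohort, stage, width = 22.5, step = 4.5,
                                    minTrials = 8, minSubjects = 11,
                                    reps = 5, folds = 5, cost = 1,
                                    seed = 1L, swsMode = "s3s4") {
  if (width <= 0 || step <= 0) stop("width and step must be positive")
  stopifnot(cohort@level == "trials")
  dur <- cohort@config@nightDuration
  startsMin <- seq(0, dur - width, by = step)
  nights <- cohort@nights
  rawStages <- cellStages(stage, swsMode)
  out <- data.frame(centreMin = startsMin + width / 2,
                    accuracy = NA_real_, nSubjects = 0L)
  for (wi in seq_along(startsMin)) {
    a <- startsMin[wi] * 60
    b <- a + width * 60
    feats <- list()
    for (nid in nights$nightId) {
      ts <- cohort@spectra[[nid]]
      sel <- ts@stage %in% rawStages & ts@onset >= a & ts@onset < b &
        !apply(ts@mask, 1, any)
      if (sum(sel) < minTrials) next
      m <- apply(ts@power[sel, , , drop = FALSE], c(2, 3), mean)
      if (anyNA(m)) next
      feats[[nid]] <- prepareFeatures(m)
    }
    keep <- nights[nights$nightId %in% names(feats), , drop = FALSE]
    both <- names(which(table(keep$subjectId) == 2L))
    keep <- keep[keep$subjectId %in% both, , drop = FALSE]
    if (length(both) < minSubjects) next
    nG <- nrow(feats[[1]])
    nB <- ncol(feats[[1]])
    X <- vapply(keep$nightId, function(nid) as.vector(feats[[nid]]),
                numeric(nG * nB))
    se <- SummarizedExperiment(
      assays = list(features = X),
      colData = DataFrame(subjectId = keep$subjectId, night = keep$night,
                          condition = keep$condition,
                          nTrials = NA_integer_,
                          row.names = keep$nightId))
    metadata(se)$stage <- stage
    metadata(se)$segment <- NA_integer_
    metadata(se)$nGroups <- nG
    metadata(se)$nBins <- nB
    res <- crossValidatedDecode(se, reps = reps, folds = folds,
                                cost = cost,
                                seed = splitSeed(seed, 20L, wi))
    out$accuracy[wi] <- validationAccuracy(res)
    out$nSubjects[wi] <- length(both)
  }
  out
}
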