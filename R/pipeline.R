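# End-to-end orchestration: simulate (or ingest) -> preprocess -> decode
# all analysis cells -> permutation inference with Holm correction ->
# sliding-window time course -> behaviour statistics.  Every stage
# receives its parameters from one RunConfig object and every output
# carries the config fingerprint, so runs are reproducible and
# attributable.

#' Pipeline run configuration
#'
#' @slot simConfig the cohort generator settings
#' @slot level cohort fidelity level ("trials", "cells", "signal")
#' @slot minTrials per-cell inclusion threshold (default 40)
#' @slot minSubjects per-cell subject minimum (default 11)
#' @slot reps decoding repetitions for the main analysis (280 at full
#'   scale)
#' @slot folds cross-validation folds (5)
#' @slot cost SVM cost C
#' @slot nPerm permutations per cell (1001 at full scale)
#' @slot permReps decoding repetitions inside the permutation engine
#' @slot windowWidth,windowStep sliding-window geometry, minutes
#' @slot timecourseStage stage for the time-course analysis ("" = skip)
#' @slot windowMinTrials per-window trial minimum
#' @slot swsMode "s3s4" or "s4"
#' @slot seed master seed
#' @export
setClass("RunConfig", representation(
  simConfig = "SimConfig", level = "character", minTrials = "numeric",
  minSubjects = "numeric", reps = "numeric", folds = "numeric",
  cost = "numeric", nPerm = "numeric", permReps = "numeric",
  windowWidth = "numeric", windowStep = "numeric",
  timecourseStage = "character", windowMinTrials = "numeric",
  swsMode = "character", seed = "integer"))

#' Construct a \linkS4class{RunConfig}
#'
#' @param simConfig a \linkS4class{SimConfig}
#' @param level,minTrials,minSubjects,reps,folds,cost,nPerm,permReps
#'   see the class slots
#' @param windowWidth,windowStep,timecourseStage,windowMinTrials,swsMode
#'   see the class slots
#' @param full use the full-scale settings (reps = 280, nPerm = 1001)
#'   instead of the reduced defaults (reps = 20, nPerm = 99)
#' @param seed master seed
#' @return A \linkS4class{RunConfig}.
#' @export
runConfig <- function(simConfig = somnidec::simConfig(), level = "trials",
                      minTrials = 40, minSubjects = 11, reps = NULL,
                      folds = 5, cost = 1, nPerm = NULL, permReps = 5,
                      windowWidth = 22.5, windowStep = 4.5,
                      timecourseStage = "SWS", windowMinTrials = 8,
                      swsMode = "s3s4", full = FALSE, seed = 1L) {
  if (is.null(reps)) reps <- if (full) 280 else 20
  if (is.null(nPerm)) nPerm <- if (full) 1001 else 99
  new("RunConfig", simConfig = simConfig, level = level,
      minTrials = minTrials, minSubjects = minSubjects, reps = reps,
      folds = folds, cost = cost, nPerm = nPerm, permReps = permReps,
      windowWidth = windowWidth, windowStep = windowStep,
      timecourseStage = timecourseStage,
      windowMinTrials = windowMinTrials, swsMode = swsMode,
      seed = as.integer(seed))
}

#' Run the full analysis pipeline
#'
#' Simulates a cohort (unless one is supplied), preprocesses signal-level
#' data, assembles per-cell features, decodes every included cell,
#' assesses significance by label permutation with Holm correction over
#' the cell family, computes the sliding-window time course, and relates
#' per-stage reprocessing strength to overnight memory consolidation.
#' Inclusion decisions (cells and subjects dropped and why) are reported
#' via messages.
#'
#' @param rc a \linkS4class{RunConfig}
#' @param cohort optional pre-built \linkS4class{SleepCohort}
#' @param outDir optional output directory for JSON/TSV summaries
#' @param runPermutations run the permutation test per cell (default TRUE)
#' @return a results bundle: list(cohort, cells, decodings, permutations,
#'   holm, timecourse, behaviour, behaviourScores, summary, fingerprint)
#' @export
runPipeline <- function(rc, cohort = NULL, outDir = NULL,
                        runPermutations = TRUE) {
  fp <- fingerprintOf(rc)
  if (is.null(cohort)) cohort <- simulateCohort(rc@simConfig, level = rc@level)
  if (cohort@level == "signal") cohort <- preprocessCohort(cohort)
  cells <- buildAllCellFeatures(cohort, minTrials = rc@minTrials,
                                minSubjects = rc@minSubjects,
                                swsMode = rc@swsMode)
  if (!length(cells))
    stop("no analysis cell satisfied the inclusion criteria ",
         "(>= ", rc@minTrials, " trials, >= ", rc@minSubjects, " subjects)")
  message(length(cells), " analysis cell(s) included: ",
          paste(names(cells), collapse = ", "))
  decodings <- list()
  permutations <- list()
  rows <- list()
  for (key in names(cells)) {
    se <- cells[[key]]
    res <- crossValidatedDecode(se, reps = rc@reps, folds = rc@folds,
                                cost = rc@cost,
                                seed = splitSeed(rc@seed, 30L, match(key, names(cells))))
    decodings[[key]] <- res
    pv <- NA_real_
    if (runPermutations && rc@nPerm > 0) {
      nd <- permutationTest(se, nPerm = rc@nPerm, reps = rc@permReps,
                            folds = rc@folds, cost = rc@cost,
                            seed = splitSeed(rc@seed, 31L, match(key, names(cells))))
      permutations[[key]] <- nd
      pv <- pValue(nd)
    }
    rows[[key]] <- data.frame(
      cell = key, stage = res@cell$stage, segment = res@cell$segment,
      nSubjects = res@nSubjects,
      validationAccuracy = validationAccuracy(res),
      trainingAccuracy = trainingAccuracy(res), p = pv)
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  if (length(permutations))
    summary$pHolm <- holmCorrect(summary$p)
  timecourse <- NULL
  if (nzchar(rc@timecourseStage) && cohort@level == "trials") {
    timecourse <- slidingWindowTimecourse(
      cohort, rc@timecourseStage, width = rc@windowWidth,
      step = rc@windowStep, minTrials = rc@windowMinTrials,
      minSubjects = rc@minSubjects, reps = rc@permReps,
      folds = rc@folds, cost = rc@cost, seed = splitSeed(rc@seed, 32L),
      swsMode = rc@swsMode)
  }
  behaviourScores <- scoreBehaviour(cohort@behaviour)
  behaviour <- relateBehaviour(decodings, behaviourScores)
  bundle <- list(cohort = cohort, cells = cells, decodings = decodings,
                 permutations = permutations, timecourse = timecourse,
                 behaviour = behaviour, behaviourScores = behaviourScores,
                 summary = summary, fingerprint = fp, seed = rc@seed)
  if (!is.null(outDir)) writeResults(bundle, outDir)
  bundle
}

#' Relate per-stage reprocessing strength to memory consolidation
#'
#' Per analysis stage, the reprocessing strength of a night is the mean
#' probability estimate over all decoded cells of that stage containing
#' the night.  Returns Spearman correlations per stage, the multi-stage
#' standardized regression, the SWS-vs-REM slope-interaction test and the
#' leverage-filtered SWS correlation.
#'
#' @param decodings named list of \linkS4class{DecodingResult} (names
#'   like "SWS_2")
#' @param behaviourScores from \code{\link{scoreBehaviour}}
#' @return list(strengths, correlations, regression, interaction,
#'   swsLeverageFiltered)
#' @export
relateBehaviour <- function(decodings, behaviourScores) {
  stages <- unique(vapply(decodings, function(d) d@cell$stage, ""))
  strengths <- data.frame(row.names = behaviourScores$nightId)
  for (st in stages) {
    acc <- setNames(numeric(nrow(behaviourScores)),
                    behaviourScores$nightId)
    cnt <- acc
    for (d in decodings) {
      if (d@cell$stage != st) next
      p <- probEstimates(d)
      common <- intersect(names(p), names(acc))
      acc[common] <- acc[common] + p[common]
      cnt[common] <- cnt[common] + 1
    }
    strengths[[st]] <- ifelse(cnt > 0, acc / pmax(cnt, 1), NA_real_)
  }
  cons <- behaviourScores$consolidation
  correlations <- lapply(stages, function(st) {
    s <- strengths[[st]]
    if (sum(complete.cases(s, cons)) < 5) return(NULL)
    spearmanRho(s, cons)
  })
  names(correlations) <- stages
  regression <- NULL
  if (ncol(strengths) >= 2 &&
      sum(complete.cases(strengths, cons)) >= 10)
    regression <- tryCatch(reprocessingRegression(strengths, cons),
                           error = function(e) NULL)
  interaction <- NULL
  if (all(c("SWS", "REM") %in% names(strengths))) {
    ok <- complete.cases(strengths$SWS, strengths$REM, cons)
    if (sum(ok) >= 4)
      interaction <- slopeInteractionTest(
        strengths$SWS[ok], strengths$REM[ok], cons[ok],
        cluster = behaviourScores$subjectId[ok],
        labels = c("SWS", "REM"))
  }
  swsLev <- NULL
  if ("SWS" %in% names(strengths)) {
    ok <- complete.cases(strengths$SWS, cons)
    if (sum(ok) >= 9) {
      x <- strengths$SWS[ok]; y <- cons[ok]
      keep <- leverageFilter(x, y, k = 3)
      swsLev <- spearmanRho(x[keep], y[keep])
    }
  }
  list(strengths = strengths, correlations = correlations,
       regression = regression, interaction = interaction,
       swsLeverageFiltered = swsLev)
}
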