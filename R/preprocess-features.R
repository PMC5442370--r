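# From cohort-level data to per-cell feature containers.  A "cell" is a
# sleep stage x 90-min segment combination; its feature container is a
# SummarizedExperiment with one column per included subject-night and one
# row per (channel group, frequency bin) feature.

#' Run the raw-signal preprocessing chain over a cohort
#'
#' Converts a signal-level cohort into a trials-level one by running, per
#' night: trial epoching, artefact screening, interpolation of bad
#' channels, Welch spectral estimation, and spatial averaging onto the
#' montage's channel groups.
#'
#' @param cohort a signal-level \linkS4class{SleepCohort}
#' @param k MAD multiplier of the artefact screen
#' @param channelBadFraction whole-channel rejection threshold
#' @return the cohort with \code{spectra} filled and \code{level="trials"}
#' @export
preprocessCohort <- function(cohort, k = 5, channelBadFraction = 0.2) {
  stopifnot(cohort@level == "signal")
  montage <- cohort@truth$montage
  for (nid in names(cohort@recordings)) {
    rec <- cohort@recordings[[nid]]
    hyp <- cohort@hypnograms[[nid]]
    tt <- epochAndLabel(rec, hyp)
    det <- detectArtefacts(rec, tt, k = k,
                           channelBadFraction = channelBadFraction)
    itp <- interpolateBadChannels(rec, det$badChannels, montage)
    # interpolated channels are usable again; isolated ones stay excluded
    mask <- det$mask
    if (length(itp$interpolated)) mask[, itp$interpolated] <- FALSE
    ts <- trialSpectra(itp$recording, tt, mask = mask)
    cohort@spectra[[nid]] <- spatialAverage(ts, montage,
                                            badChannels = itp$excluded)
  }
  cohort@level <- "trials"
  cohort
}

#' Assemble the feature container of one analysis cell
#'
#' For every subject-night, averages the artefact-free trial spectra of
#' the cell, then normalizes each channel to [0, 1] and applies the
#' spectral sharpening filter, yielding a 32 x 60 feature matrix.  A
#' subject-night enters only with at least \code{minTrials} clean trials;
#' a subject enters only with both nights (the paired, counterbalanced
#' design the between-subject classifier relies on).  The cell is analysed
#' only when at least \code{minSubjects} subjects qualify.
#'
#' @param cohort a trials- or cells-level \linkS4class{SleepCohort}
#' @param stage "S2", "SWS" or "REM"
#' @param segment 90-min segment index
#' @param minTrials per-night inclusion threshold (default 40)
#' @param minSubjects per-cell inclusion threshold (default 11)
#' @param swsMode "s3s4" (default) or "s4"
#' @return a \link[SummarizedExperiment]{SummarizedExperiment} (features x
#'   nights) with rowData (group, freq), colData (subjectId, night,
#'   condition, nTrials) and metadata (stage, segment), or NULL when the
#'   cell fails inclusion
#' @export
buildCellFeatures <- function(cohort, stage, segment, minTrials = 40,
                              minSubjects = 11, swsMode = "s3s4") {
  nights <- cohort@nights
  feats <- list()
  ntr <- list()
  if (cohort@level == "signal")
    stop("run preprocessCohort() first for signal-level cohorts")
  for (nid in nights$nightId) {
    m <- NULL
    if (cohort@level == "trials") {
      ts <- cohort@spectra[[nid]]
      if (!is.null(ts))
        m <- aggregateCell(ts, stage, segment, minTrials = minTrials,
                           swsMode = swsMode)
    } else {
      key <- paste(stage, segment, sep = "_")
      cm <- cohort@cellMeans[[key]]
      if (!is.null(cm)) {
        r <- match(nid, nights$nightId)
        if (cm$nTrials[nid] >= minTrials && !anyNA(cm$power[r, , ])) {
          m <- matrix(cm$power[r, , ], dim(cm$power)[2], dim(cm$power)[3])
          attr(m, "nTrials") <- cm$nTrials[nid]
        }
      }
    }
    if (is.null(m) || anyNA(m)) next
    feats[[nid]] <- prepareFeatures(m)
    ntr[[nid]] <- attr(m, "nTrials")
  }
  keep <- names(feats)
  sub <- nights[nights$nightId %in% keep, , drop = FALSE]
  both <- names(which(table(sub$subjectId) == 2L))
  sub <- sub[sub$subjectId %in% both, , drop = FALSE]
  if (length(both) < minSubjects) return(NULL)
  nG <- nrow(feats[[1]])
  freqs <- analysisFreqs()[seq_len(ncol(feats[[1]]))]
  X <- vapply(sub$nightId, function(nid) as.vector(feats[[nid]]),
              numeric(nG * length(freqs)))
  rd <- DataFrame(group = rep(seq_len(nG), times = length(freqs)),
                  freq = rep(freqs, each = nG))
  cd <- DataFrame(subjectId = sub$subjectId, night = sub$night,
                  condition = sub$condition,
                  nTrials = unlist(ntr[sub$nightId]),
                  row.names = sub$nightId)
  se <- SummarizedExperiment(assays = list(features = X),
                             rowData = rd, colData = cd)
  metadata(se)$stage <- stage
  metadata(se)$segment <- segment
  metadata(se)$nGroups <- nG
  metadata(se)$nBins <- length(freqs)
  se
}

#' Feature containers for every analysis cell of a cohort
#'
#' @inheritParams buildCellFeatures
#' @param stages analysis stages (default S2, SWS, REM)
#' @return named list (e.g. \code{"SWS_2"}) of SummarizedExperiments;
#'   cells failing inclusion are omitted
#' @export
buildAllCellFeatures <- function(cohort, stages = c("S2", "SWS", "REM"),
                                 minTrials = 40, minSubjects = 11,
                                 swsMode = "s3s4") {
  nSeg <- floor(cohort@config@nightDuration / 90)
  out <- list()
  for (st in stages) {
    for (sg in seq_len(nSeg)) {
      se <- buildCellFeatures(cohort, st, sg, minTrials, minSubjects,
                              swsMode)
      if (!is.null(se)) out[[paste(st, sg, sep = "_")]] <- se
    }
  }
  out
}

# nights x groups x bins array from a cell's SummarizedExperiment
featuresArray <- function(se) {
  nG <- metadata(se)$nGroups
  nB <- metadata(se)$nBins
  X <- assay(se, "features")
  arr <- array(t(X), c(ncol(X), nG, nB))
  dimnames(arr) <- list(colnames(se), NULL, NULL)
  arr
}
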