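# Cohort assembly.  Three fidelity levels trade physical realism against
# compute:
#  "signal": raw multichannel time series per night (full pipeline incl.
#            Welch estimation and artefact screening runs on it);
#  "trials": per-trial group-level spectra with multiplicative log-normal
#            noise emulating single-trial Welch estimation error;
#  "cells":  per-cell mean spectra sampled directly with the noise scale
#            of a mean over the cell's trial count.
# All levels share hypnograms, the signature model, behaviour and truth.

# Per-subject stage templates at group resolution (groups x bins).
# Between-subject variability is modelled as primarily regional: every
# (subject, group) draws its own smooth 1/f-tilt and band-gain
# perturbation, on top of a small globally shared band gain.  Keeping the
# shared (cross-group) component small is deliberate: under the
# accuracy-weighted channel average, variability that is common to all
# groups cannot be averaged away and is statistically confounded with a
# band-confined signature, whereas regional variability both challenges
# the per-channel classifiers and is attenuated by spatial averaging.
subjectStageTemplates <- function(config, subject, nGroups,
                                  freqs = analysisFreqs()) {
  subjOff <- subjectBandOffsets(config, subject, 0L)
  tpl <- list()
  tiltFac <- matrix(0, nGroups, length(freqs))
  offs <- vector("list", nGroups)
  for (g in seq_len(nGroups)) {
    tilt <- withSeed(splitSeed(config@seed, 310L, subject, g),
                     rnorm(1, 0, config@subjectTiltSd))
    tiltFac[g, ] <- (freqs / 6)^tilt
    offs[[g]] <- subjOff + subjectBandOffsets(config, subject, g)
  }
  for (st in c("S2", "S3", "S4", "REM", "W", "S1", "MT")) {
    m <- matrix(0, nGroups, length(freqs))
    for (g in seq_len(nGroups)) {
      m[g, ] <- stageSpectrumTemplate(st, freqs, offs[[g]]) * tiltFac[g, ]
    }
    tpl[[st]] <- m
  }
  tpl
}

# analysis stages x segments present in a night table
analysisCellKeys <- function(nSegments, stages = c("S2", "SWS", "REM")) {
  as.vector(outer(stages, seq_len(nSegments), paste, sep = "_"))
}

#' Simulate a synthetic sleep-EEG cohort
#'
#' Generates \code{nSubjects} subjects with two counterbalanced nights
#' each (one face, one house), per-night hypnograms, spectral data at the
#' requested fidelity level, recognition-memory behaviour coupled to the
#' realized signature strength, and a ground-truth record.  Identical
#' configs (including the seed) yield identical cohorts.
#'
#' @param config a \linkS4class{SimConfig}
#' @param level fidelity level: "trials" (per-trial group spectra,
#'   default), "cells" (per-cell means) or "signal" (raw recordings)
#' @return A \linkS4class{SleepCohort}.
#' @examples
#' coh <- simulateCohort(simConfig(nSubjects = 4, nightDuration = 90,
#'                                 trialStride = 8L), level = "cells")
#' coh
#' @export
simulateCohort <- function(config, level = c("trials", "cells", "signal")) {
  level <- match.arg(level)
  ns <- config@nSubjects
  subjects <- sprintf("s%02d", seq_len(ns))
  nights <- data.frame(
    subjectId = rep(subjects, each = 2L),
    night = rep(1:2, ns),
    condition = as.vector(vapply(seq_len(ns), function(i) {
      if (i %% 2 == 1) c("face", "house") else c("house", "face")
    }, character(2))))
  nights$nightId <- paste0(nights$subjectId, "_n", nights$night)
  freqs <- analysisFreqs()
  nG <- if (level == "signal") config@nRawChannels else config@nGroups
  hypnograms <- list()
  spectra <- list()
  recordings <- list()
  cellMeans <- list()
  realized <- setNames(numeric(nrow(nights)), nights$nightId)
  montage <- if (level == "signal")
    makeSyntheticMontage(config@nRawChannels) else NULL
  homeGroup <- NULL
  if (level == "signal") {
    D <- arcDist(as.matrix(montage$centres[, c("x", "y", "z")]),
                 as.matrix(montage$electrodes[, c("x", "y", "z")]),
                 montage$headRadius)
    homeGroup <- apply(D, 2, which.min)
  }
  nSeg <- floor(config@nightDuration / 90)
  for (r in seq_len(nrow(nights))) {
    sid <- nights$subjectId[r]
    si <- match(sid, subjects)
    ni <- nights$night[r]
    cond <- nights$condition[r]
    nid <- nights$nightId[r]
    hyp <- generateHypnogram(config@nightDuration,
                             splitSeed(config@seed, 100L, si, ni))
    hypnograms[[nid]] <- hyp
    # realized strength is partly trait-like: a subject component (80% of
    # the variance) plus a night-specific component
    zS <- withSeed(splitSeed(config@seed, 200L, si),
                   rnorm(1, 0, sqrt(0.8) * config@amplitudeGainSd))
    zN <- withSeed(splitSeed(config@seed, 201L, si, ni),
                   rnorm(1, 0, sqrt(0.2) * config@amplitudeGainSd))
    amp <- config@signatureAmplitude * exp(zS + zN)
    realized[nid] <- amp
    if (ni == 1L || !exists("tplCacheSubj") || tplCacheSubj != si) {
      tpl <- subjectStageTemplates(config, si, config@nGroups, freqs)
      tplCacheSubj <- si
    }
    if (level == "trials") {
      tt <- hypnogramTrialTable(hyp, stride = config@trialStride)
      tt <- tt[tt$stage %in% c("S2", "S3", "S4", "REM"), , drop = FALSE]
      nT <- nrow(tt)
      pow <- array(NA_real_, c(nT, config@nGroups, length(freqs)))
      withSeed(splitSeed(config@seed, 600L, si, ni), {
        sdv <- config@trialNoiseSd
        for (st in unique(tt$stage)) {
          for (sg in unique(tt$segment[tt$stage == st])) {
            idx <- which(tt$stage == st &
                           (is.na(tt$segment) == is.na(sg)) &
                           (is.na(sg) | tt$segment %in% sg))
            if (!length(idx)) next
            base <- applySignature(tpl[[st]], config, cond, st,
                                   if (is.na(sg)) NA_integer_ else sg,
                                   freqs, amplitude = amp)
            k <- length(idx)
            noise <- exp(sdv * rnorm(k * config@nGroups * length(freqs)) -
                           sdv^2 / 2)
            pow[idx, , ] <- aperm(array(base, c(config@nGroups,
                                                length(freqs), k)),
                                  c(3, 1, 2)) *
              array(noise, c(k, config@nGroups, length(freqs)))
          }
        }
      })
      spectra[[nid]] <- new("TrialSpectra", power = pow, freqs = freqs,
                            onset = tt$onset, stage = tt$stage,
                            segment = tt$segment,
                            mask = matrix(FALSE, nT, config@nGroups),
                            channelNames = paste0("G", seq_len(config@nGroups)))
    } else if (level == "cells") {
      tt <- hypnogramTrialTable(hyp, stride = config@trialStride)
      withSeed(splitSeed(config@seed, 600L, si, ni), {
        sdv <- config@trialNoiseSd
        for (stg in c("S2", "SWS", "REM")) {
          raw <- cellStages(stg)
          for (sg in seq_len(nSeg)) {
            idx <- which(tt$stage %in% raw & !is.na(tt$segment) &
                           tt$segment == sg)
            n <- length(idx)
            key <- paste(stg, sg, sep = "_")
            if (is.null(cellMeans[[key]]))
              cellMeans[[key]] <- list(
                power = array(NA_real_, c(nrow(nights), config@nGroups,
                                          length(freqs))),
                nTrials = setNames(integer(nrow(nights)), nights$nightId))
            cellMeans[[key]]$nTrials[nid] <- n
            if (n == 0L) next
            # trial-count-weighted mix of the raw stage templates
            base <- 0
            for (rs in raw) {
              w <- sum(tt$stage[idx] == rs) / n
              if (w > 0) base <- base + w * tpl[[rs]]
            }
            base <- applySignature(base, config, cond, raw[which.max(
              tabulate(match(tt$stage[idx], raw)))], sg, freqs,
              amplitude = amp)
            relSd <- sdv / sqrt(n)
            noise <- 1 + relSd * rnorm(config@nGroups * length(freqs))
            cellMeans[[key]]$power[r, , ] <- base *
              matrix(pmax(noise, 0.05), config@nGroups, length(freqs))
          }
        }
      })
    } else { # signal
      ampLocal <- amp
      elecGain <- withSeed(splitSeed(config@seed, 700L, si),
                           exp(rnorm(config@nRawChannels, 0, 0.05)))
      tiltG <- vapply(seq_len(max(homeGroup)), function(g)
        withSeed(splitSeed(config@seed, 310L, si, g),
                 rnorm(1, 0, config@subjectTiltSd)), 0)
      segOfEpoch <- function(e) {
        sg <- floor(((e - 1) * hyp@epochLength) / (90 * 60)) + 1
        if (sg > nSeg) NA_integer_ else as.integer(sg)
      }
      spectrumFun <- function(stage, ch, epoch) {
        sg <- segOfEpoch(epoch)
        g <- homeGroup[ch]
        function(f) {
          base <- stageSpectrumTemplate(stage, f,
                                        subjectBandOffsets(config, si, 0L)) *
            elecGain[ch] * (pmax(f, 0.5) / 6)^tiltG[g]
          delta <- signatureDelta(config, cond, stage, sg, f,
                                  nGroups = max(homeGroup),
                                  amplitude = ampLocal)[g, ]
          if (config@signatureMode == "multiplicative") base * (1 + delta)
          else base + delta
        }
      }
      recordings[[nid]] <- synthesizeRecording(
        hyp, config, spectrumFun, nChannels = config@nRawChannels,
        channelNames = montage$electrodes$name, subjectId = sid,
        night = ni, condition = cond,
        seed = splitSeed(config@seed, 800L, si, ni))
    }
  }
  behaviour <- generateBehaviour(config, realized,
                                 nights = nights,
                                 seed = splitSeed(config@seed, 900L))
  new("SleepCohort", nights = nights, level = level,
      hypnograms = hypnograms, spectra = spectra, recordings = recordings,
      cellMeans = cellMeans, behaviour = behaviour,
      truth = list(realizedStrength = realized,
                   signatureCells = config@signatureCells,
                   signatureSegments = config@signatureSegments,
                   signatureStages = config@signatureStages,
                   montage = montage),
      config = config)
}

#' Generate recognition-memory outcomes coupled to signature strength
#'
#' For every subject-night, draws pre- and post-sleep recognition counts
#' such that the expected overnight consolidation is
#' \code{intercept + behaviourLink * strength + noise} (d' units).
#' Pre-sleep sensitivity is drawn around d' = 1.7; hit and false-alarm
#' counts are binomial with rates implied by an unbiased criterion, so
#' all count bounds (hits <= nOld, falseAlarms <= nNew) hold by
#' construction.
#'
#' @param config a \linkS4class{SimConfig} (link, intercept, noise, item
#'   counts)
#' @param realizedStrengths named numeric, one realized signature strength
#'   per subject-night (names = nightId)
#' @param nights data.frame(nightId, subjectId, night); defaults to names
#'   of \code{realizedStrengths}
#' @param seed RNG seed
#' @return data.frame(subjectId, night, session, nOld, nNew, hits,
#'   falseAlarms), two rows (pre, post) per night
#' @export
generateBehaviour <- function(config, realizedStrengths, nights = NULL,
                              seed = 1L) {
  stopifnot(is.finite(config@behaviourLink))
  ids <- names(realizedStrengths)
  if (is.null(nights)) {
    nights <- data.frame(nightId = ids,
                         subjectId = sub("_n[12]$", "", ids),
                         night = as.integer(sub("^.*_n", "", ids)))
  }
  out <- withSeed(seed, {
    rows <- list()
    for (i in seq_along(ids)) {
      dPre <- rnorm(1, 1.7, 0.3)
      delta <- config@behaviourIntercept +
        config@behaviourLink * realizedStrengths[i] +
        rnorm(1, 0, config@behaviourNoise)
      dPost <- dPre + delta
      for (ses in c("pre", "post")) {
        d <- if (ses == "pre") dPre else dPost
        hr <- pnorm(d / 2)
        far <- pnorm(-d / 2)
        rows[[length(rows) + 1L]] <- data.frame(
          subjectId = nights$subjectId[nights$nightId == ids[i]],
          night = nights$night[nights$nightId == ids[i]],
          session = ses, nOld = config@nOld, nNew = config@nNew,
          hits = rbinom(1, config@nOld, hr),
          falseAlarms = rbinom(1, config@nNew, far))
      }
    }
    do.call(rbind, rows)
  })
  rownames(out) <- NULL
  out
}
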