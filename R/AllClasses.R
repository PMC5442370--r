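#' Simulation configuration for synthetic sleep-EEG cohorts
#'
#' Holds every parameter of the synthetic cohort generator: cohort size,
#' recording geometry, the condition-specific spectral signature (where it
#' sits, how strong it is, in which sleep stages and 90-min segments it is
#' expressed), artefact rates, and the coupling of overnight memory
#' consolidation to realized signature strength.
#'
#' @slot nSubjects number of subjects (each contributes two nights)
#' @slot samplingRate sampling rate in Hz
#' @slot nRawChannels number of raw electrodes
#' @slot nGroups number of averaged channel groups emitted by the
#'   spectrum-level generator paths
#' @slot nightDuration night length in minutes
#' @slot signatureAmplitude dimensionless effect size of the condition
#'   signature (power multiplied by 1 + s * amplitude, s = +1 face / -1 house)
#' @slot signatureCells data.frame with columns \code{group}, \code{fLo},
#'   \code{fHi}: the (channel group x frequency band) cells carrying
#'   condition information
#' @slot signatureSegments integer 90-min segment indices expressing the
#'   signature
#' @slot signatureStages sleep stages expressing the signature
#' @slot signatureMode "multiplicative" (default) or "additive"
#' @slot amplitudeGainSd sd of the per-subject-night log-normal gain on the
#'   signature amplitude (realized strength heterogeneity)
#' @slot subjectTiltSd sd of the per-subject-per-group 1/f-tilt exponent
#'   (smooth regional between-subject spectral variance)
#' @slot subjectGainSd sd of the globally shared per-subject band gains
#' @slot groupGainSd sd of per-subject-per-group log-normal band gains
#' @slot trialNoiseSd sd of the log-normal multiplicative noise on single
#'   4-s trial spectra (Welch estimation noise)
#' @slot artefactRates named numeric: \code{disconnect} (per channel),
#'   \code{jump}, \code{muscle} (per trial)
#' @slot behaviourLink slope coupling consolidation (delta d') to realized
#'   signature strength
#' @slot behaviourIntercept intercept of the consolidation model
#' @slot behaviourNoise sd of the consolidation noise (d' units)
#' @slot nOld,nNew recognition-test item counts (old, new) per session
#' @slot trialStride keep every \code{trialStride}-th 4-s trial in the
#'   spectrum-level generator (1 = all trials)
#' @slot seed master seed; identical configs are bitwise reproducible
#' @export
setClass("SimConfig", representation(
  nSubjects = "integer", samplingRate = "numeric", nRawChannels = "integer",
  nGroups = "integer", nightDuration = "numeric",
  signatureAmplitude = "numeric", signatureCells = "data.frame",
  signatureSegments = "integer", signatureStages = "character",
  signatureMode = "character", amplitudeGainSd = "numeric",
  subjectTiltSd = "numeric",
  subjectGainSd = "numeric", groupGainSd = "numeric",
  trialNoiseSd = "numeric", artefactRates = "numeric",
  behaviourLink = "numeric", behaviourIntercept = "numeric",
  behaviourNoise = "numeric", nOld = "integer", nNew = "integer",
  trialStride = "integer", seed = "integer"))

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@nSubjects < 2L) msg <- c(msg, "nSubjects must be >= 2")
  if (object@signatureAmplitude < 0)
    msg <- c(msg, "signatureAmplitude must be >= 0")
  if (any(object@artefactRates < 0 | object@artefactRates > 1))
    msg <- c(msg, "artefact rates must lie in [0, 1]")
  if (!all(c("disconnect", "jump", "muscle") %in% names(object@artefactRates)))
    msg <- c(msg, "artefactRates needs entries disconnect, jump, muscle")
  if (!object@signatureMode %in% c("multiplicative", "additive"))
    msg <- c(msg, "signatureMode must be multiplicative or additive")
  if (!all(object@signatureStages %in% STAGE_LEVELS))
    msg <- c(msg, "signatureStages outside stage vocabulary")
  if (nrow(object@signatureCells) &&
      !all(c("group", "fLo", "fHi") %in% names(object@signatureCells)))
    msg <- c(msg, "signatureCells needs columns group, fLo, fHi")
  if (!is.finite(object@behaviourLink))
    msg <- c(msg, "behaviourLink must be finite")
  if (object@nightDuration <= 0) msg <- c(msg, "nightDuration must be > 0")
  if (length(msg)) msg else TRUE
})

#' Construct a \linkS4class{SimConfig}
#'
#' Defaults describe the emulated study design: 128-electrode recordings,
#' 480-min nights, a multiplicative condition signature of amplitude 0.5
#' confined to one channel group in the spindle band during the second
#' 90-min segment of S2/SWS sleep, and consolidation coupled to realized
#' signature strength.
#'
#' @param nSubjects subjects in the cohort (two nights each)
#' @param samplingRate Hz (default 250; the 0.5--30 Hz analysis needs no more)
#' @param nRawChannels raw electrodes (default 128)
#' @param nGroups averaged channel groups for spectrum-level generation
#' @param nightDuration minutes (default 480)
#' @param signatureAmplitude effect size (default 0.5)
#' @param signatureCells data.frame(group, fLo, fHi); default: group 7,
#'   spindle band 11--15.5 Hz
#' @param signatureSegments segments carrying the signature (default 2)
#' @param signatureStages stages carrying it (default S2, S3, S4)
#' @param signatureMode "multiplicative" or "additive"
#' @param amplitudeGainSd per-night log-normal amplitude gain sd (default 0.5)
#' @param subjectTiltSd per-subject-per-group spectral tilt exponent sd
#'   (default 0.02)
#' @param subjectGainSd globally shared per-subject band gain sd
#'   (default 0.005)
#' @param groupGainSd per-subject-per-group band gain sd (default 0.015)
#' @param trialNoiseSd single-trial spectral noise sd (default 0.5)
#' @param artefactRates named numeric (disconnect, jump, muscle)
#' @param behaviourLink consolidation slope on realized strength (default 3)
#' @param behaviourIntercept consolidation intercept (default 0)
#' @param behaviourNoise consolidation noise sd in d' units (default 0.15)
#' @param nOld,nNew recognition item counts (default 100 old, 50 new)
#' @param trialStride trial thinning factor (default 1)
#' @param seed master seed
#' @return A validated \linkS4class{SimConfig}.
#' @export
simConfig <- function(nSubjects = 32L, samplingRate = 250, nRawChannels = 128L,
                      nGroups = 32L, nightDuration = 480,
                      signatureAmplitude = 0.5,
                      signatureCells = data.frame(group = 7L, fLo = 11, fHi = 15.5),
                      signatureSegments = 2L,
                      signatureStages = c("S2", "S3", "S4"),
                      signatureMode = "multiplicative",
                      amplitudeGainSd = 0.5, subjectTiltSd = 0.02,
                      subjectGainSd = 0.005,
                      groupGainSd = 0.015, trialNoiseSd = 0.5,
                      artefactRates = c(disconnect = 0, jump = 0, muscle = 0),
                      behaviourLink = 3, behaviourIntercept = 0,
                      behaviourNoise = 0.15, nOld = 100L, nNew = 50L,
                      trialStride = 1L, seed = 1L) {
  new("SimConfig", nSubjects = as.integer(nSubjects),
      samplingRate = samplingRate, nRawChannels = as.integer(nRawChannels),
      nGroups = as.integer(nGroups), nightDuration = nightDuration,
      signatureAmplitude = signatureAmplitude,
      signatureCells = signatureCells,
      signatureSegments = as.integer(signatureSegments),
      signatureStages = signatureStages, signatureMode = signatureMode,
      amplitudeGainSd = amplitudeGainSd, subjectTiltSd = subjectTiltSd,
      subjectGainSd = subjectGainSd,
      groupGainSd = groupGainSd, trialNoiseSd = trialNoiseSd,
      artefactRates = artefactRates, behaviourLink = behaviourLink,
      behaviourIntercept = behaviourIntercept, behaviourNoise = behaviourNoise,
      nOld = as.integer(nOld), nNew = as.integer(nNew),
      trialStride = as.integer(trialStride), seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nSubjects, "subjects x 2 nights,",
      object@nightDuration, "min nights @", object@samplingRate, "Hz\n")
  cat("  signature: amplitude", object@signatureAmplitude, "(",
      object@signatureMode, ") in", nrow(object@signatureCells),
      "cell(s), segments", paste(object@signatureSegments, collapse = ","),
      ", stages", paste(object@signatureStages, collapse = ","), "\n")
  cat("  behaviour link:", object@behaviourLink, " seed:", object@seed, "\n")
})

#' Hypnogram: per-30-s-epoch sleep-stage labels for one night
#'
#' @slot stages character vector of stage labels (W, S1, S2, S3, S4, REM, MT)
#' @slot epochLength epoch length in seconds (30)
#' @slot lightsOff clock origin in seconds (0 = lights off)
#' @export
setClass("Hypnogram", representation(
  stages = "character", epochLength = "numeric", lightsOff = "numeric"))

setValidity("Hypnogram", function(object) {
  if (!all(object@stages %in% STAGE_LEVELS))
    return(paste("unknown stage label(s):",
                 paste(unique(setdiff(object@stages, STAGE_LEVELS)),
                       collapse = ", ")))
  if (object@epochLength <= 0) return("epochLength must be > 0")
  TRUE
})

#' @describeIn Hypnogram stage labels
#' @param x,object a Hypnogram
#' @export
setGeneric("stages", function(x) standardGeneric("stages"))
#' @rdname Hypnogram-class
#' @export
setMethod("stages", "Hypnogram", function(x) x@stages)

#' @rdname Hypnogram-class
#' @export
setGeneric("nightMinutes", function(x) standardGeneric("nightMinutes"))
#' @rdname Hypnogram-class
#' @export
setMethod("nightMinutes", "Hypnogram",
          function(x) length(x@stages) * x@epochLength / 60)

setMethod("show", "Hypnogram", function(object) {
  tab <- table(factor(object@stages, levels = STAGE_LEVELS))
  cat("Hypnogram:", length(object@stages), "epochs of",
      object@epochLength, "s (", nightMinutes(object), "min )\n")
  print(tab)
})

#' Multichannel EEG recording with metadata
#'
#' @slot signal channels x samples matrix, microvolts
#' @slot samplingRate Hz
#' @slot channelNames electrode labels (rownames of signal)
#' @slot subjectId subject identifier
#' @slot night night index (1 or 2)
#' @slot condition learned category: "face" or "house" (NA allowed)
#' @export
setClass("EEGRecording", representation(
  signal = "matrix", samplingRate = "numeric", channelNames = "character",
  subjectId = "character", night = "integer", condition = "character"))

setValidity("EEGRecording", function(object) {
  if (nrow(object@signal) != length(object@channelNames))
    return("channel count does not match channelNames")
  if (object@samplingRate <= 0) return("samplingRate must be > 0")
  if (!object@condition %in% c("face", "house", NA_character_))
    return("condition must be face, house or NA")
  TRUE
})

#' @rdname EEGRecording-class
#' @param x,object an EEGRecording
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @rdname EEGRecording-class
#' @export
setMethod("samplingRate", "EEGRecording", function(x) x@samplingRate)

setMethod("show", "EEGRecording", function(object) {
  cat("EEGRecording:", nrow(object@signal), "channels x",
      ncol(object@signal), "samples @", object@samplingRate, "Hz",
      sprintf("(%.1f min)", ncol(object@signal) / object@samplingRate / 60),
      "\n  subject", object@subjectId, "night", object@night,
      "condition", object@condition, "\n")
})

#' Per-trial channel x frequency-bin power spectra
#'
#' Power in microvolt^2/Hz for non-overlapping 4-s trials, at raw-electrode
#' or group-channel resolution, with per-trial stage/segment labels, trial
#' onsets and an artefact mask.
#'
#' @slot power trials x channels x bins array (>= 0 outside artefacts)
#' @slot freqs frequency-bin centres, Hz
#' @slot onset trial onset, seconds from lights off
#' @slot stage sleep stage per trial
#' @slot segment 90-min segment index per trial (NA beyond the last full one)
#' @slot mask logical trials x channels artefact mask (TRUE = contaminated)
#' @slot channelNames channel labels
#' @export
setClass("TrialSpectra", representation(
  power = "array", freqs = "numeric", onset = "numeric", stage = "character",
  segment = "integer", mask = "matrix", channelNames = "character"))

setValidity("TrialSpectra", function(object) {
  d <- dim(object@power)
  if (length(d) != 3L) return("power must be trials x channels x bins")
  if (d[3] != length(object@freqs)) return("bin count mismatch with freqs")
  if (d[1] != length(object@stage) || d[1] != length(object@onset) ||
      d[1] != length(object@segment))
    return("trial label lengths do not match power")
  if (!all(dim(object@mask) == d[1:2])) return("mask dims must be trials x channels")
  TRUE
})

setMethod("show", "TrialSpectra", function(object) {
  d <- dim(object@power)
  cat("TrialSpectra:", d[1], "trials x", d[2], "channels x", d[3], "bins (",
      min(object@freqs), "-", max(object@freqs), "Hz)\n  stages:",
      paste(names(table(object@stage)), collapse = ", "),
      "; flagged trial-channels:", sum(object@mask), "\n")
})

#' Result of the two-step cross-validated decoding of one analysis cell
#'
#' @slot validationAccuracy mean accuracy on held-out subjects
#' @slot trainingAccuracy mean accuracy on training subjects
#' @slot probEstimates per-night mean calibrated probability assigned to the
#'   night's true condition, averaged over all repetitions
#' @slot innerWeights channels x bins mean absolute per-channel SVM weights
#' @slot outerWeights length-bins mean absolute main-SVM weights
#' @slot channelWeights mean per-channel inner-loop accuracies (the weights)
#' @slot cell list(stage, segment)
#' @slot nSubjects subjects entering the analysis
#' @slot reps,folds,cost cross-validation settings
#' @slot seed RNG seed of the run
#' @slot fingerprint md5 of the decoding configuration
#' @export
setClass("DecodingResult", representation(
  validationAccuracy = "numeric", trainingAccuracy = "numeric",
  probEstimates = "numeric", innerWeights = "matrix",
  outerWeights = "numeric", channelWeights = "numeric", cell = "list",
  nSubjects = "integer", reps = "integer", folds = "integer",
  cost = "numeric", seed = "integer", fingerprint = "character"))

setValidity("DecodingResult", function(object) {
  msg <- character()
  if (object@validationAccuracy < 0 || object@validationAccuracy > 1)
    msg <- c(msg, "validationAccuracy outside [0, 1]")
  if (any(object@probEstimates < 0 | object@probEstimates > 1))
    msg <- c(msg, "probability estimates outside [0, 1]")
  if (any(object@channelWeights < 0 | object@channelWeights > 1))
    msg <- c(msg, "channel weights outside [0, 1]")
  if (length(msg)) msg else TRUE
})

#' @rdname DecodingResult-class
#' @param x,object a DecodingResult
#' @export
setGeneric("validationAccuracy", function(x) standardGeneric("validationAccuracy"))
#' @rdname DecodingResult-class
#' @export
setMethod("validationAccuracy", "DecodingResult", function(x) x@validationAccuracy)

#' @rdname DecodingResult-class
#' @export
setGeneric("trainingAccuracy", function(x) standardGeneric("trainingAccuracy"))
#' @rdname DecodingResult-class
#' @export
setMethod("trainingAccuracy", "DecodingResult", function(x) x@trainingAccuracy)

#' @rdname DecodingResult-class
#' @export
setGeneric("probEstimates", function(x) standardGeneric("probEstimates"))
#' @rdname DecodingResult-class
#' @export
setMethod("probEstimates", "DecodingResult", function(x) x@probEstimates)

#' @rdname DecodingResult-class
#' @export
setGeneric("innerWeights", function(x) standardGeneric("innerWeights"))
#' @rdname DecodingResult-class
#' @export
setMethod("innerWeights", "DecodingResult", function(x) x@innerWeights)

setMethod("show", "DecodingResult", function(object) {
  cat(sprintf(
    "DecodingResult [%s, segment %s]: validation %.3f, training %.3f\n",
    object@cell$stage, object@cell$segment,
    object@validationAccuracy, object@trainingAccuracy))
  cat("  ", object@nSubjects, "subjects,", object@reps, "reps x",
      object@folds, "folds, C =", object@cost, "\n")
})

#' Label-permutation null distribution for a decoding accuracy
#'
#' @slot accuracies null accuracies (one per permutation)
#' @slot observed observed accuracy
#' @slot pValue permutation p-value (#\{null >= observed\} / nPerm; when the
#'   count is zero this is 1/nPerm and \code{bound} is TRUE, i.e. p < 1/nPerm)
#' @slot bound TRUE when pValue is a strict upper bound
#' @slot nPerm number of permutations
#' @slot fingerprint md5 of the decoding configuration used for both the
#'   observed statistic and every permutation
#' @export
setClass("NullDistribution", representation(
  accuracies = "numeric", observed = "numeric", pValue = "numeric",
  bound = "logical", nPerm = "integer", fingerprint = "character"))

setValidity("NullDistribution", function(object) {
  if (object@pValue <= 0 || object@pValue > 1)
    return("pValue must lie in (0, 1]")
  if (length(object@accuracies) != object@nPerm)
    return("accuracies length must equal nPerm")
  TRUE
})

#' @rdname NullDistribution-class
#' @param x,object a NullDistribution
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))
#' @rdname NullDistribution-class
#' @export
setMethod("pValue", "NullDistribution", function(x) x@pValue)

#' @rdname NullDistribution-class
#' @export
setGeneric("nullAccuracies", function(x) standardGeneric("nullAccuracies"))
#' @rdname NullDistribution-class
#' @export
setMethod("nullAccuracies", "NullDistribution", function(x) x@accuracies)

setMethod("show", "NullDistribution", function(object) {
  cat(sprintf("NullDistribution: observed %.3f, %s%.4g (%d permutations)\n",
              object@observed, if (object@bound) "p < " else "p = ",
              object@pValue, object@nPerm))
})

#' Synthetic sleep-EEG cohort
#'
#' Container produced by \code{\link{simulateCohort}}.  Depending on the
#' fidelity level it holds raw recordings (\code{"signal"}), per-trial
#' group-level spectra (\code{"trials"}), or directly sampled per-cell mean
#' spectra (\code{"cells"}), plus hypnograms, behaviour and ground truth.
#'
#' @slot nights data.frame: nightId, subjectId, night, condition
#' @slot level fidelity level: "signal", "trials" or "cells"
#' @slot hypnograms named list of \linkS4class{Hypnogram}
#' @slot spectra named list of \linkS4class{TrialSpectra} (trials level)
#' @slot recordings named list of \linkS4class{EEGRecording} (signal level)
#' @slot cellMeans cells-level store: cellKey -> list(power, nTrials)
#' @slot behaviour recognition outcomes, long format (one row per
#'   night x session)
#' @slot truth list: realizedStrength per night, artefact masks, signature
#' @slot config the generating \linkS4class{SimConfig}
#' @export
setClass("SleepCohort", representation(
  nights = "data.frame", level = "character", hypnograms = "list",
  spectra = "list", recordings = "list", cellMeans = "list",
  behaviour = "data.frame", truth = "list", config = "SimConfig"))

setValidity("SleepCohort", function(object) {
  if (!object@level %in% c("signal", "trials", "cells"))
    return("level must be signal, trials or cells")
  tab <- table(object@nights$subjectId, object@nights$condition)
  if (!all(tab == 1L))
    return("each subject must have exactly one face and one house night")
  TRUE
})

setMethod("show", "SleepCohort", function(object) {
  cat("SleepCohort (level =", object@level, "):",
      length(unique(object@nights$subjectId)), "subjects,",
      nrow(object@nights), "nights\n")
  show(object@config)
})
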