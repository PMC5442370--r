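# Stage-dependent EEG power spectrum templates: a 1/f-decaying baseline
# plus stage-specific spectral landmarks (delta dominance in S3/S4, a
# ~13 Hz spindle peak in S2 and SWS, a ~6 Hz theta bump in REM, alpha in
# wake).  Units are microvolt^2/Hz.  Templates are defined for any
# frequency > 0 so that raw-signal synthesis can evaluate them on an
# arbitrary FFT grid; below 0.5 Hz the baseline is held flat.

gaussBump <- function(f, mu, sdev) exp(-0.5 * ((f - mu) / sdev)^2)

#' Stage-dependent power spectral density template
#'
#' @param stage a sleep stage label (W, S1, S2, S3, S4, REM, MT)
#' @param freqs frequencies in Hz at which to evaluate (default: the 60
#'   analysis bins 0.5, 1.0, ..., 30 Hz)
#' @param subjectOffsets optional named numeric of per-band log-gains
#'   (names from \code{\link{frequencyBands}}); applied multiplicatively as
#'   \code{exp(offset)} within each band
#' @return strictly positive numeric vector of PSD values, microvolt^2/Hz
#' @examples
#' s4 <- stageSpectrumTemplate("S4")
#' s4[2] > s4[40]  # delta dominates beta in deep sleep
#' @export
stageSpectrumTemplate <- function(stage, freqs = analysisFreqs(),
                                  subjectOffsets = NULL) {
  if (length(stage) != 1L || !stage %in% STAGE_LEVELS)
    stop("unknown sleep stage: ", paste(stage, collapse = ","))
  f <- pmax(freqs, 0.5)
  base <- 30 / f^1.2
  p <- switch(stage,
    W   = base * 0.8 + 10 * gaussBump(f, 10, 1.0),
    S1  = base * 0.9 + 4 * gaussBump(f, 5.5, 1.5),
    S2  = base + 40 * gaussBump(f, 1.5, 1.0) + 25 * gaussBump(f, 13, 1.0),
    S3  = base + 150 * gaussBump(f, 1.25, 0.8) + 55 * gaussBump(f, 13, 1.0),
    S4  = base + 250 * gaussBump(f, 1.25, 0.8) + 75 * gaussBump(f, 13, 1.0),
    REM = base * 0.9 + 12 * gaussBump(f, 6, 1.2),
    MT  = base * 3)
  if (!is.null(subjectOffsets)) {
    bands <- frequencyBands()
    for (bn in names(subjectOffsets)) {
      if (!bn %in% names(bands)) next
      idx <- freqs >= bands[[bn]][1] & freqs <= bands[[bn]][2]
      p[idx] <- p[idx] * exp(subjectOffsets[[bn]])
    }
  }
  p
}

# per-subject (and optionally per-group) band log-offsets, deterministic
# in (seed, subject, group)
subjectBandOffsets <- function(config, subject, group = 0L) {
  sdv <- if (group == 0L) config@subjectGainSd else config@groupGainSd
  bands <- names(frequencyBands())
  off <- withSeed(splitSeed(config@seed, 300L, subject, group),
                  rnorm(length(bands), 0, sdv))
  setNames(off, bands)
}

# signed perturbation matrix (groups x bins): s * amplitude inside the
# configured signature cells when (stage, segment) qualify, 0 elsewhere
signatureDelta <- function(config, condition, stage, segment,
                           freqs = analysisFreqs(),
                           nGroups = config@nGroups,
                           amplitude = config@signatureAmplitude) {
  delta <- matrix(0, nGroups, length(freqs))
  if (amplitude == 0) return(delta)
  if (is.null(stage) || is.null(segment) || is.na(segment) ||
      !stage %in% config@signatureStages ||
      !segment %in% config@signatureSegments) return(delta)
  s <- if (condition == "face") 1 else -1
  cells <- config@signatureCells
  for (r in seq_len(nrow(cells))) {
    g <- cells$group[r]
    if (g > nGroups) next
    idx <- freqs >= cells$fLo[r] & freqs <= cells$fHi[r]
    delta[g, idx] <- s * amplitude
  }
  delta
}

# apply the signature to a groups x bins power matrix
applySignature <- function(power, config, condition, stage, segment,
                           freqs = analysisFreqs(),
                           amplitude = config@signatureAmplitude) {
  delta <- signatureDelta(config, condition, stage, segment, freqs,
                          nGroups = nrow(power), amplitude = amplitude)
  if (config@signatureMode == "multiplicative") power * (1 + delta)
  else power + delta  # absolute perturbation, microvolt^2/Hz
}

#' Embed the condition-specific spectral signature
#'
#' Multiplies power inside the configured signature cells (channel-group x
#' frequency-band locations) by \code{1 + s * amplitude}, with \code{s = +1}
#' for the face condition and \code{s = -1} for house, but only for trials
#' whose stage and 90-min segment are configured to express the signature.
#' All other entries are returned unchanged.  With
#' \code{signatureMode = "additive"} the perturbation is
#' \code{s * amplitude * power} added within the cells only when the trial
#' qualifies (identical first-order effect, kept for comparison).
#'
#' @param spectra a groups x bins power matrix or a
#'   \linkS4class{TrialSpectra} object (group-channel resolution)
#' @param config a \linkS4class{SimConfig}; \code{signatureAmplitude < 0}
#'   is rejected by the config validity
#' @param condition "face" or "house"
#' @param stage,segment context for a plain matrix input (ignored for
#'   TrialSpectra, which carry their own labels)
#' @return object of the same class as \code{spectra}
#' @export
embedConditionSignature <- function(spectra, config, condition,
                                    stage = NULL, segment = NULL) {
  stopifnot(condition %in% c("face", "house"))
  if (is(spectra, "TrialSpectra")) {
    d <- dim(spectra@power)
    for (t in seq_len(d[1])) {
      spectra@power[t, , ] <- applySignature(
        matrix(spectra@power[t, , ], d[2], d[3]), config, condition,
        spectra@stage[t], spectra@segment[t], spectra@freqs)
    }
    return(spectra)
  }
  applySignature(spectra, config, condition, stage, segment,
                 freqs = analysisFreqs()[seq_len(ncol(spectra))])
}
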