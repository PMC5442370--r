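# Trial epoching and artefact screening on raw recordings.

# 4-s trials tiled inside each 30-s scoring epoch (7 whole trials per
# epoch; the 2-s remainder is dropped), labelled with the epoch's stage
# and with the 90-min segment of the trial onset.  Only full 90-min
# segments exist; onsets beyond the last full segment get NA.
hypnogramTrialTable <- function(hypnogram, trialLen = 4, segmentLen = 90,
                                stride = 1L) {
  el <- hypnogram@epochLength
  perEpoch <- floor(el / trialLen)
  stg <- stages(hypnogram)
  nE <- length(stg)
  onset <- rep((seq_len(nE) - 1) * el, each = perEpoch) +
    rep((seq_len(perEpoch) - 1) * trialLen, times = nE)
  stage <- rep(stg, each = perEpoch)
  nSeg <- floor(nightMinutes(hypnogram) / segmentLen)
  segment <- floor(onset / (segmentLen * 60)) + 1L
  segment[segment > nSeg] <- NA_integer_
  tt <- data.frame(trial = seq_along(onset), onset = onset, stage = stage,
                   segment = as.integer(segment))
  if (stride > 1L) tt <- tt[seq(1L, nrow(tt), by = stride), , drop = FALSE]
  rownames(tt) <- NULL
  tt
}

#' Split a recording into labelled 4-s trials
#'
#' Tiles non-overlapping trials of \code{trialLen} seconds inside each
#' 30-s scoring epoch (7 whole trials fit; the remainder is dropped).
#' Each trial inherits the sleep stage of its containing epoch and the
#' 90-min segment of its onset, counted from lights off.  Trials starting
#' after the last full segment carry segment NA.
#'
#' @param recording an \linkS4class{EEGRecording}
#' @param hypnogram the night's \linkS4class{Hypnogram}; must cover the
#'   recording
#' @param trialLen trial length in seconds (default 4)
#' @param segmentLen segment length in minutes (default 90)
#' @return data.frame(trial, onset, stage, segment)
#' @export
epochAndLabel <- function(recording, hypnogram, trialLen = 4,
                          segmentLen = 90) {
  recDur <- ncol(recording@signal) / recording@samplingRate
  if (nightMinutes(hypnogram) * 60 < recDur - 1e-9)
    stop("hypnogram does not cover the recording")
  tt <- hypnogramTrialTable(hypnogram, trialLen, segmentLen)
  tt[tt$onset + trialLen <= recDur + 1e-9, , drop = FALSE]
}

# per-trial x channel statistic matrices used by the artefact screen
trialChannelStats <- function(recording, trialTable, trialLen = 4,
                              muscleBand = c(110, 140)) {
  sig <- recording@signal
  fs <- recording@samplingRate
  nCh <- nrow(sig)
  nT <- nrow(trialTable)
  ns <- as.integer(round(trialLen * fs))
  logPower <- matrix(NA_real_, nT, nCh)
  jump <- matrix(NA_real_, nT, nCh)
  muscle <- if (fs >= 2 * muscleBand[2]) matrix(NA_real_, nT, nCh) else NULL
  if (!is.null(muscle)) {
    fgrid <- (0:(ns - 1)) * fs / ns
    mb <- which(fgrid >= muscleBand[1] & fgrid <= muscleBand[2])
  }
  for (t in seq_len(nT)) {
    a <- as.integer(round(trialTable$onset[t] * fs)) + 1L
    x <- sig[, a:(a + ns - 1L), drop = FALSE]
    logPower[t, ] <- log(rowMeans(x^2) + 1e-12)
    jump[t, ] <- apply(abs(x[, -1L, drop = FALSE] -
                             x[, -ns, drop = FALSE]), 1, max)
    if (!is.null(muscle)) {
      X <- mvfft(t(x))
      muscle[t, ] <- colMeans(abs(X[mb, , drop = FALSE])^2) / (ns * fs)
    }
  }
  list(logPower = logPower, jump = jump, muscle = muscle)
}

#' Screen trials and channels for artefacts
#'
#' Computes three per-trial, per-channel statistics -- overall (log)
#' spectral power, maximal sample-to-sample amplitude change, and
#' 110--140 Hz band power -- and flags outliers beyond
#' median +/- k * MAD.  Disconnected electrodes are caught at the channel
#' level (a channel whose median log power is an outlier across channels);
#' jump and muscle statistics are screened per channel across trials
#' (one-sided, high).  Channels flagged in more than
#' \code{channelBadFraction} of trials are marked bad as a whole.  The
#' muscle criterion needs a sampling rate of at least twice the band's
#' upper edge and is skipped with a warning otherwise.
#'
#' @param recording an \linkS4class{EEGRecording}
#' @param trialTable output of \code{\link{epochAndLabel}}
#' @param k MAD multiplier (default 5)
#' @param channelBadFraction fraction of flagged trials above which a
#'   channel is bad as a whole (default 0.2)
#' @param trialLen trial length in seconds
#' @param muscleBand muscle-artefact frequency band, Hz
#' @return list(mask = trials x channels logical, badChannels = integer,
#'   trialBad = logical per trial (any good-channel flag), stats)
#' @export
detectArtefacts <- function(recording, trialTable, k = 5,
                            channelBadFraction = 0.2, trialLen = 4,
                            muscleBand = c(110, 140)) {
  st <- trialChannelStats(recording, trialTable, trialLen, muscleBand)
  if (is.null(st$muscle) && recording@samplingRate < 2 * muscleBand[2])
    warning("sampling rate too low for the muscle criterion; skipped")
  nT <- nrow(st$logPower)
  nCh <- ncol(st$logPower)
  mask <- matrix(FALSE, nT, nCh)
  # channel-level disconnection screen: outlying median log power
  chMed <- apply(st$logPower, 2, median)
  dev <- abs(chMed - median(chMed))
  badChannels <- which(dev > k * mad(chMed) + 1e-12)
  flagHigh <- function(m) {
    med <- apply(m, 2, median)
    s <- apply(m, 2, mad)
    sweep(sweep(m, 2, med), 2, pmax(s, 1e-12), "/") > k
  }
  # within-channel screens across trials
  mask <- mask | flagHigh(st$jump)
  mask <- mask | flagHigh(st$logPower)
  if (!is.null(st$muscle)) mask <- mask | flagHigh(st$muscle)
  badFrac <- colMeans(mask)
  badChannels <- sort(union(badChannels, which(badFrac > channelBadFraction)))
  if (length(badChannels)) mask[, badChannels] <- TRUE
  good <- setdiff(seq_len(nCh), badChannels)
  trialBad <- if (length(good))
    apply(mask[, good, drop = FALSE], 1, any) else rep(TRUE, nT)
  if (all(trialBad))
    stop("artefact screen flagged every trial; check recording quality ",
         "or the MAD multiplier k")
  list(mask = mask, badChannels = badChannels, trialBad = trialBad,
       stats = st)
}

#' Interpolate channels marked bad as a whole
#'
#' Replaces each bad channel by the inverse-distance-weighted mean of the
#' good electrodes within twice the montage grouping radius.  A bad
#' channel with fewer than 3 good neighbours cannot be interpolated; it is
#' returned in \code{excluded} and should be dropped from its channel
#' group instead.
#'
#' @param recording an \linkS4class{EEGRecording}
#' @param badChannels integer indices of bad channels
#' @param montage montage from \code{\link{makeSyntheticMontage}}
#' @return list(recording, interpolated = integer, excluded = integer)
#' @export
interpolateBadChannels <- function(recording, badChannels, montage) {
  if (!length(badChannels))
    return(list(recording = recording, interpolated = integer(0),
                excluded = integer(0)))
  D <- electrodeDistances(montage)
  good <- setdiff(seq_len(nrow(recording@signal)), badChannels)
  excluded <- integer(0)
  done <- integer(0)
  for (ch in badChannels) {
    nb <- good[D[ch, good] <= 2 * montage$groupRadius]
    if (length(nb) < 3L) {
      excluded <- c(excluded, ch)
      next
    }
    w <- 1 / pmax(D[ch, nb], 1e-6)
    recording@signal[ch, ] <-
      as.numeric(w %*% recording@signal[nb, , drop = FALSE]) / sum(w)
    done <- c(done, ch)
  }
  if (length(excluded))
    message("channel(s) ", paste(excluded, collapse = ","),
            " isolated; excluded from their groups instead of interpolated")
  list(recording = recording, interpolated = done, excluded = excluded)
}
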