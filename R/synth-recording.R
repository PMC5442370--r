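# Raw-signal synthesis: per 30-s epoch, Gaussian noise is spectrally
# shaped to the epoch's stage template by inverse-FFT synthesis (random
# phases, amplitudes following the target PSD), and consecutive epochs are
# joined with a 0.5-s equal-power crossfade.  The realized Welch spectrum
# of concatenated same-stage epochs converges to the template as duration
# grows.

# One segment of shaped noise: n samples, psd evaluated on the rfft
# grid.  Amplitudes are fixed at the target PSD and only phases are
# random (the classic surrogate-data construction): each segment then
# realizes the template spectrum exactly at FFT resolution, so Welch
# estimates converge quickly, while the time-domain signal remains
# asymptotically Gaussian.
shapedNoise <- function(n, psdFun, fs) {
  nf <- floor(n / 2)
  f <- (1:nf) * fs / n
  S <- psdFun(f)
  # |X_k|^2 = n * fs * S / 2 gives one-sided periodogram == S exactly
  amp <- sqrt(n * fs * S / 2)
  z <- exp(2i * pi * runif(nf))
  Xh <- amp * z
  if (n %% 2 == 0) Xh[nf] <- complex(real = sqrt(n * fs * S[nf]) *
                                       sign(runif(1) - 0.5))
  X <- complex(length.out = n)
  idx <- 2:(nf + 1)
  X[idx] <- Xh
  conjIdx <- n - idx + 2
  keep <- conjIdx != idx  # skip the self-conjugate Nyquist bin
  X[conjIdx[keep]] <- Conj(Xh[keep])
  Re(fft(X, inverse = TRUE)) / n
}

#' Synthesize a raw multichannel recording from a hypnogram
#'
#' Emits, per 30-s epoch, Gaussian noise spectrally shaped to the epoch
#' stage's PSD template (per channel), with 0.5-s crossfades at epoch
#' joins.  \code{spectrumFun(stage)} must return a function of frequency
#' (Hz) giving the per-channel PSD; by default all channels share
#' \code{\link{stageSpectrumTemplate}}.
#'
#' @param hypnogram a \linkS4class{Hypnogram}; must be non-empty
#' @param config a \linkS4class{SimConfig} (sampling rate, channel count)
#' @param spectrumFun function(stage, channel, epoch) -> function(freqHz)
#'   -> PSD; default uses the stage templates for every channel (the
#'   epoch index lets callers vary the spectrum across the night)
#' @param nChannels number of channels (default \code{config@nRawChannels})
#' @param channelNames channel labels
#' @param subjectId,night,condition recording metadata
#' @param seed RNG seed (fixed seed gives an identical signal)
#' @return An \linkS4class{EEGRecording}.
#' @export
synthesizeRecording <- function(hypnogram, config,
                                spectrumFun = NULL,
                                nChannels = config@nRawChannels,
                                channelNames = paste0("E", seq_len(nChannels)),
                                subjectId = "s01", night = 1L,
                                condition = NA_character_,
                                seed = config@seed) {
  if (length(stages(hypnogram)) == 0L) stop("empty hypnogram")
  fs <- config@samplingRate
  if (is.null(spectrumFun))
    spectrumFun <- function(stage, channel, epoch)
      function(f) stageSpectrumTemplate(stage, f)
  epochN <- as.integer(round(hypnogram@epochLength * fs))
  cfN <- as.integer(round(0.5 * fs))
  stg <- stages(hypnogram)
  nTot <- epochN * length(stg)
  sig <- matrix(0, nChannels, nTot)
  fadeIn <- sin(seq(0, pi / 2, length.out = cfN))^2
  withSeed(splitSeed(seed, 400L), {
    for (ch in seq_len(nChannels)) {
      x <- numeric(nTot + cfN)
      pos <- 1L
      for (e in seq_along(stg)) {
        st <- stg[e]
        seg <- shapedNoise(epochN + cfN, spectrumFun(st, ch, e), fs)
        idx <- pos:(pos + epochN + cfN - 1L)
        if (pos == 1L) {
          x[idx] <- seg
        } else {
          ov <- pos:(pos + cfN - 1L)
          x[ov] <- x[ov] * rev(fadeIn) + seg[seq_len(cfN)] * fadeIn
          x[(pos + cfN):(pos + epochN + cfN - 1L)] <- seg[(cfN + 1L):(epochN + cfN)]
        }
        pos <- pos + epochN
      }
      sig[ch, ] <- x[seq_len(nTot)]
    }
  })
  rownames(sig) <- channelNames
  new("EEGRecording", signal = sig, samplingRate = fs,
      channelNames = channelNames, subjectId = subjectId,
      night = as.integer(night), condition = condition)
}

#' Inject synthetic artefacts into a recording
#'
#' Inserts, at the configured rates, the three artefact families the
#' rejection stage screens for: disconnected electrodes (whole channels
#' going flat or noise-dominated), sudden amplitude jumps (step
#' discontinuities within a 4-s trial) and muscle artefacts (110--140 Hz
#' bursts; requires a sampling rate of at least 280 Hz and is skipped with
#' a warning otherwise).  Returns the contaminated recording together with
#' the ground-truth mask for detector validation.
#'
#' @param recording an \linkS4class{EEGRecording}
#' @param artefactRates named numeric with entries \code{disconnect} (per
#'   channel), \code{jump} and \code{muscle} (per 4-s trial)
#' @param seed RNG seed
#' @param trialLen trial length in seconds (default 4)
#' @return list(recording, mask = trials x channels logical,
#'   badChannels = integer indices, trialOnsets = seconds)
#' @export
injectArtefacts <- function(recording, artefactRates, seed = 1L,
                            trialLen = 4, epochLength = 30) {
  stopifnot(all(artefactRates >= 0), all(artefactRates <= 1))
  fs <- recording@samplingRate
  sig <- recording@signal
  nCh <- nrow(sig)
  nTrialSamp <- as.integer(round(trialLen * fs))
  # trials on the same epoch-tiled grid the preprocessing stage uses
  perEpoch <- floor(epochLength / trialLen)
  nEpochs <- floor(ncol(sig) / (epochLength * fs))
  onsets <- rep((seq_len(nEpochs) - 1) * epochLength, each = perEpoch) +
    rep((seq_len(perEpoch) - 1) * trialLen, times = nEpochs)
  nTrials <- length(onsets)
  startIdx <- as.integer(round(onsets * fs)) + 1L
  mask <- matrix(FALSE, nTrials, nCh)
  badChannels <- integer(0)
  rms <- sqrt(mean(sig[1, ]^2))
  withSeed(splitSeed(seed, 500L), {
    r <- artefactRates
    if (r[["disconnect"]] > 0) {
      dead <- which(runif(nCh) < r[["disconnect"]])
      for (ch in dead) {
        flat <- runif(1) < 0.5
        sig[ch, ] <- if (flat) rnorm(ncol(sig), 0, rms * 1e-3)
                      else rnorm(ncol(sig), 0, rms * 50)
      }
      badChannels <- dead
      if (length(dead)) mask[, dead] <- TRUE
    }
    if (r[["jump"]] > 0 && nTrials > 0) {
      hit <- which(runif(nTrials) < r[["jump"]])
      for (t in hit) {
        ch <- sample.int(nCh, 1L)
        a <- startIdx[t]
        j <- a + sample.int(nTrialSamp - 2L, 1L)
        sig[ch, j:(a + nTrialSamp - 1L)] <-
          sig[ch, j:(a + nTrialSamp - 1L)] + 8 * rms
        mask[t, ch] <- TRUE
      }
    }
    if (r[["muscle"]] > 0 && nTrials > 0) {
      if (fs < 280) {
        warning("sampling rate below 280 Hz: muscle artefacts not injected")
      } else {
        hit <- which(runif(nTrials) < r[["muscle"]])
        emgPsd <- function(f) ifelse(f >= 110 & f <= 140, 1, 0) *
          (10 * rms^2 / 30)
        for (t in hit) {
          ch <- sample.int(nCh, 1L)
          a <- startIdx[t]
          burst <- shapedNoise(nTrialSamp, emgPsd, fs)
          sig[ch, a:(a + nTrialSamp - 1L)] <-
            sig[ch, a:(a + nTrialSamp - 1L)] + burst
          mask[t, ch] <- TRUE
        }
      }
    }
  })
  recording@signal <- sig
  list(recording = recording, mask = mask, badChannels = badChannels,
       trialOnsets = onsets)
}
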