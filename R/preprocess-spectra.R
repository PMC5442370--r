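# Spectral estimation and the feature-preparation chain:
# Welch PSD -> spatial averaging onto 32 channel groups -> per-cell trial
# averaging -> per-channel zero-one normalization -> spectral sharpening.
# The order is fixed; permuting normalization and sharpening changes the
# features and is rejected by the test suite.

#' Welch power spectral density of one trial
#'
#' Averages Hamming-windowed periodograms over all full 2-s windows at
#' 95 percent overlap.  With 2-s windows the bin spacing is 0.5 Hz at any
#' sampling rate; bins at 0.5, 1.0, ..., \code{fmax} Hz are returned (the
#' 0 Hz bin is discarded), i.e. 60 bins up to the 30 Hz analysis ceiling.
#'
#' @param x numeric vector (samples) or samples x channels matrix
#' @param fs sampling rate, Hz
#' @param window window length in seconds (default 2)
#' @param overlap fractional window overlap in [0, 1) (default 0.95)
#' @param fmax highest retained frequency, Hz (default 30)
#' @return bins x channels matrix of PSD values (microvolt^2/Hz) with a
#'   \code{freqs} attribute; a vector input gives a 1-column matrix
#' @examples
#' fs <- 250; t <- seq(0, 4 - 1/fs, by = 1/fs)
#' p <- welchPsd(sin(2 * pi * 10 * t), fs)
#' attr(p, "freqs")[which.max(p)]  # 10 Hz
#' @export
welchPsd <- function(x, fs, window = 2, overlap = 0.95, fmax = 30) {
  if (is.vector(x)) x <- matrix(x, ncol = 1L)
  n <- nrow(x)
  L <- as.integer(round(window * fs))
  if (overlap >= 1 || overlap < 0) stop("overlap must lie in [0, 1)")
  if (L > n) stop("window longer than the trial")
  step <- max(1L, as.integer(round(L * (1 - overlap))))
  starts <- seq.int(1L, n - L + 1L, by = step)
  w <- signal::hamming(L)
  U <- sum(w^2)
  acc <- matrix(0, floor(L / 2) + 1L, ncol(x))
  for (s in starts) {
    seg <- x[s:(s + L - 1L), , drop = FALSE] * w
    X <- mvfft(seg)
    P <- abs(X[seq_len(nrow(acc)), , drop = FALSE])^2
    acc <- acc + P
  }
  psd <- acc / (length(starts) * fs * U)
  # one-sided: double everything except DC and (for even L) Nyquist
  dbl <- rep(2, nrow(psd))
  dbl[1L] <- 1
  if (L %% 2 == 0) dbl[length(dbl)] <- 1
  psd <- psd * dbl
  freqs <- (seq_len(nrow(psd)) - 1L) * fs / L
  keep <- freqs >= 0.5 - 1e-9 & freqs <= fmax + 1e-9
  out <- psd[keep, , drop = FALSE]
  attr(out, "freqs") <- freqs[keep]
  out
}

#' Per-trial Welch spectra for a whole recording
#'
#' Runs \code{\link{welchPsd}} on every labelled trial and assembles a
#' \linkS4class{TrialSpectra} object at raw-electrode resolution.
#'
#' @param recording an \linkS4class{EEGRecording}
#' @param trialTable from \code{\link{epochAndLabel}}
#' @param mask optional trials x channels artefact mask
#' @param trialLen trial length in seconds
#' @inheritParams welchPsd
#' @return A \linkS4class{TrialSpectra}.
#' @export
trialSpectra <- function(recording, trialTable, mask = NULL, trialLen = 4,
                         window = 2, overlap = 0.95, fmax = 30) {
  fs <- recording@samplingRate
  ns <- as.integer(round(trialLen * fs))
  nT <- nrow(trialTable)
  nCh <- nrow(recording@signal)
  first <- welchPsd(recording@signal[1, seq_len(ns)], fs, window, overlap, fmax)
  freqs <- attr(first, "freqs")
  pow <- array(NA_real_, c(nT, nCh, length(freqs)))
  for (t in seq_len(nT)) {
    a <- as.integer(round(trialTable$onset[t] * fs)) + 1L
    p <- welchPsd(t(recording@signal[, a:(a + ns - 1L), drop = FALSE]),
                  fs, window, overlap, fmax)
    pow[t, , ] <- t(p)
  }
  if (is.null(mask)) mask <- matrix(FALSE, nT, nCh)
  new("TrialSpectra", power = pow, freqs = freqs,
      onset = trialTable$onset, stage = trialTable$stage,
      segment = trialTable$segment, mask = mask,
      channelNames = recording@channelNames)
}

#' Average raw-electrode spectra onto the 32 channel groups
#'
#' For every trial and frequency bin, the group value is the mean over the
#' group's member electrodes that are neither bad as a whole nor flagged
#' for that trial.  A group left without a single good member yields NA
#' for the affected trials (the subject-night is then excluded from cells
#' that need the group).
#'
#' @param ts a \linkS4class{TrialSpectra} at electrode resolution
#' @param montage montage defining the 32 groups
#' @param badChannels electrodes excluded entirely
#' @return A \linkS4class{TrialSpectra} with one channel per group.
#' @export
spatialAverage <- function(ts, montage, badChannels = integer(0)) {
  d <- dim(ts@power)
  groups <- montage$membership
  nG <- length(groups)
  pow <- array(NA_real_, c(d[1], nG, d[3]))
  gmask <- matrix(FALSE, d[1], nG)
  for (g in seq_len(nG)) {
    mem <- setdiff(groups[[g]], badChannels)
    if (!length(mem)) {
      gmask[, g] <- TRUE
      next
    }
    flg <- ts@mask[, mem, drop = FALSE]
    # mean over good members per trial and bin; all-flagged -> NA
    for (b in seq_len(d[3])) {
      m <- matrix(ts@power[, mem, b], d[1], length(mem))
      m[flg] <- NA
      pow[, g, b] <- rowMeans(m, na.rm = TRUE)
    }
    gmask[, g] <- apply(flg, 1, all)
  }
  pow[is.nan(pow)] <- NA_real_
  new("TrialSpectra", power = pow, freqs = ts@freqs, onset = ts@onset,
      stage = ts@stage, segment = ts@segment, mask = gmask,
      channelNames = names(groups))
}

#' Mean spectrum of one analysis cell
#'
#' Averages a subject-night's artefact-free trial spectra over all trials
#' belonging to one analysis cell (sleep stage x 90-min segment).  The
#' subject-night is excluded from the cell (NULL is returned) when fewer
#' than \code{minTrials} clean trials are available, i.e. less than
#' \code{minTrials * 4} s of data.
#'
#' @param ts group-level \linkS4class{TrialSpectra}
#' @param stage analysis stage: "S2", "REM", "SWS" (S3+S4 pooled) or "S4"
#' @param segment 90-min segment index
#' @param minTrials inclusion threshold (default 40)
#' @param trialBad optional logical: trials to exclude wholesale
#' @param swsMode "s3s4" pools S3 and S4 into SWS; "s4" restricts to S4
#' @return channels x bins matrix with attribute \code{nTrials}, or NULL
#'   if the cell fails the inclusion criterion
#' @export
aggregateCell <- function(ts, stage, segment, minTrials = 40,
                          trialBad = NULL, swsMode = c("s3s4", "s4")) {
  swsMode <- match.arg(swsMode)
  rawStages <- cellStages(stage, swsMode)
  sel <- ts@stage %in% rawStages & !is.na(ts@segment) &
    ts@segment == segment
  if (!is.null(trialBad)) sel <- sel & !trialBad
  sel <- sel & !apply(ts@mask, 1, any)
  n <- sum(sel)
  if (n < minTrials) return(NULL)
  m <- apply(ts@power[sel, , , drop = FALSE], c(2, 3), mean)
  attr(m, "nTrials") <- n
  m
}

# raw stage labels making up an analysis stage
cellStages <- function(stage, swsMode = "s3s4") {
  switch(stage,
         SWS = if (swsMode == "s3s4") c("S3", "S4") else "S4",
         stage)
}

#' Normalize each channel's spectrum to [0, 1]
#'
#' Per channel (row), maps the minimum over the 60 bins to 0 and the
#' maximum to 1.  This removes amplitude differences between channels
#' (reference-distance effects) and general between-subject power
#' differences.  A constant channel maps to all zeros with a warning.
#'
#' @param m channels x bins matrix
#' @return matrix of the same shape, rows in [0, 1]
#' @export
normalizeChannels <- function(m) {
  rmin <- apply(m, 1, min)
  rmax <- apply(m, 1, max)
  rng <- rmax - rmin
  flat <- rng <= 0
  if (any(flat)) {
    warning(sum(flat), " constant channel(s) normalized to all zeros")
    rng[flat] <- 1
  }
  out <- (m - rmin) / rng
  out[flat, ] <- 0
  out
}

#' Spectral sharpening filter
#'
#' Subtracts from every bin the moving average of its six neighbouring
#' bins (three on each side, centre excluded, truncated at the spectrum
#' edges).  This removes the smooth baseline spectrum and accentuates
#' narrow-band deviations; output values may be negative.
#'
#' @param m channels x bins matrix (>= 7 bins)
#' @param halfWidth neighbours per side (default 3)
#' @return matrix of the same shape
#' @examples
#' sharpenSpectrum(matrix(1:10, 1))  # interior of a ramp -> 0
#' @export
sharpenSpectrum <- function(m, halfWidth = 3L) {
  if (is.vector(m)) m <- matrix(m, 1L)
  nb <- ncol(m)
  if (nb < 2 * halfWidth + 1) stop("need at least ", 2 * halfWidth + 1, " bins")
  out <- m
  for (j in seq_len(nb)) {
    idx <- setdiff(max(1L, j - halfWidth):min(nb, j + halfWidth), j)
    out[, j] <- m[, j] - rowMeans(m[, idx, drop = FALSE])
  }
  out
}

# the fixed preparation order: normalize, then sharpen
prepareFeatures <- function(cellMean) sharpenSpectrum(normalizeChannels(cellMean))
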