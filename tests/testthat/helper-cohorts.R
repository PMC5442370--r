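# Shared fixtures: small cohorts and configs built in code.

smallConfig <- function(...) {
  simConfig(nSubjects = 12L, nightDuration = 480, trialStride = 8L,
            seed = 42L, ...)
}

# a tiny signal-level config for raw-pipeline tests
tinySignalConfig <- function(...) {
  simConfig(nSubjects = 2L, samplingRate = 250, nRawChannels = 16L,
            nightDuration = 30, seed = 7L, ...)
}

# cells-level cohort cached across tests within a file
cellsCohort <- local({
  cache <- new.env()
  function(key = "default", ...) {
    if (is.null(cache[[key]])) {
      cfg <- simConfig(nSubjects = 12L, trialStride = 4L, seed = 42L, ...)
      cache[[key]] <- simulateCohort(cfg, level = "cells")
    }
    cache[[key]]
  }
})

# deterministic toy feature container for decode tests:
# nSubjects subjects x 2 nights, nGroups x nBins features, with an
# optional class separation delta added to `signalGroup` bins
toyFeatureSE <- function(nSubjects = 6, nGroups = 2, nBins = 3,
                         delta = 1, signalGroup = 1, sd = 0.2,
                         seed = 1) {
  set.seed(seed)
  subj <- rep(sprintf("s%02d", seq_len(nSubjects)), each = 2)
  night <- rep(1:2, nSubjects)
  cond <- unlist(lapply(seq_len(nSubjects), function(i)
    if (i %% 2) c("face", "house") else c("house", "face")))
  nightId <- paste0(subj, "_n", night)
  X <- matrix(rnorm(nGroups * nBins * length(subj), sd = sd),
              nGroups * nBins, length(subj))
  sgn <- ifelse(cond == "face", 1, -1)
  rows <- signalGroup + (seq_len(nBins) - 1) * nGroups
  X[rows, ] <- X[rows, ] + rep(sgn, each = nBins) * delta / 2
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = X),
    colData = S4Vectors::DataFrame(subjectId = subj, night = night,
                                   condition = cond, nTrials = 50L,
                                   row.names = nightId))
  S4Vectors::metadata(se)$stage <- "S2"
  S4Vectors::metadata(se)$segment <- 1L
  S4Vectors::metadata(se)$nGroups <- nGroups
  S4Vectors::metadata(se)$nBins <- nBins
  se
}
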