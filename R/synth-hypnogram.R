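# Hypnogram generation: a cyclic stage template with ~90-min period.
# Every full 90-min segment of the night contains S2, SWS (S3/S4) and REM
# epochs, so each analysis cell can be populated.  Across cycles SWS
# shrinks and REM grows, mimicking the usual overnight redistribution.

# per-cycle stage durations in minutes (sum = 90)
cycleTemplate <- function(cycle) {
  s4 <- max(25 - 7 * (cycle - 1), 4)
  rem <- min(10 + 6 * (cycle - 1), 32)
  w <- if (cycle == 1) 2 else 0.5
  s1 <- if (cycle == 1) 4 else 2
  s3a <- 8
  s3b <- 4
  rest <- 90 - (w + s1 + s4 + rem + s3a + s3b)
  s2a <- round(rest * 0.6, 1)
  s2b <- rest - s2a
  data.frame(stage = c("W", "S1", "S2", "S3", "S4", "S3", "S2", "REM"),
             minutes = c(w, s1, s2a, s3a, s4, s3b, s2b, rem))
}

# convert jittered minute durations to epoch counts preserving the total
minutesToEpochs <- function(minutes, epochsTotal) {
  frac <- minutes / sum(minutes) * epochsTotal
  n <- floor(frac)
  rem <- epochsTotal - sum(n)
  if (rem > 0) {
    ord <- order(frac - n, decreasing = TRUE)
    n[ord[seq_len(rem)]] <- n[ord[seq_len(rem)]] + 1L
  }
  as.integer(n)
}

#' Generate a synthetic hypnogram
#'
#' Produces a 30-s-epoch stage sequence following a cyclic template
#' (descent W -> S1 -> S2 -> S3 -> S4, re-ascent, REM) with a cycle period
#' of 90 min.  Stage durations are jittered (+/- 10 percent) per cycle
#' under the given seed; the total per cycle stays 90 min, so each full
#' 90-min segment contains S2, SWS and REM sleep.
#'
#' @param duration night duration in minutes; must be a positive multiple
#'   of 0.5 (the 30-s epoch length)
#' @param seed RNG seed; identical seeds give identical hypnograms
#' @param epochLength epoch length in seconds (default 30)
#' @return A \linkS4class{Hypnogram}.
#' @examples
#' h <- generateHypnogram(480, seed = 1)
#' table(stages(h))
#' @export
generateHypnogram <- function(duration = 480, seed = 1L, epochLength = 30) {
  if (!is.numeric(duration) || duration <= 0)
    stop("duration must be > 0 minutes")
  if (abs(duration * 60 / epochLength - round(duration * 60 / epochLength)) > 1e-9)
    stop("duration must be a multiple of the 30-s epoch length")
  nEpochs <- as.integer(round(duration * 60 / epochLength))
  epochsPerCycle <- as.integer(round(90 * 60 / epochLength))
  nCycles <- ceiling(nEpochs / epochsPerCycle)
  out <- withSeed(splitSeed(seed, 101L), {
    labs <- character(0)
    for (cy in seq_len(nCycles)) {
      tpl <- cycleTemplate(cy)
      jit <- tpl$minutes * runif(nrow(tpl), 0.9, 1.1)
      n <- minutesToEpochs(jit, epochsPerCycle)
      labs <- c(labs, rep(tpl$stage, times = n))
    }
    labs[seq_len(nEpochs)]
  })
  new("Hypnogram", stages = out, epochLength = epochLength, lightsOff = 0)
}
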