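# The synthetic cohort generator: hypnograms, spectral templates, the
# condition signature, raw-signal synthesis, artefact injection and
# behaviour coupling.

test_that("hypnograms follow the cyclic template and are reproducible", {
  h <- generateHypnogram(480, seed = 1)
  expect_length(stages(h), 960)           # 480 min / 30 s
  expect_true(all(stages(h) %in% c("W", "S1", "S2", "S3", "S4", "REM", "MT")))
  # every full 90-min segment contains S2, SWS and REM epochs
  seg <- rep(1:5, each = 180)
  for (s in 1:5) {
    st <- stages(h)[seg == s]
    expect_true(all(c("S2", "REM") %in% st) && any(c("S3", "S4") %in% st),
                label = paste("segment", s, "stage coverage"))
  }
  # a single 90-min night still covers the stage sequence
  for (sd in c(2, 9, 33)) {
    h90 <- generateHypnogram(90, seed = sd)
    expect_true(all(c("S2", "S4", "REM") %in% stages(h90)))
  }
  expect_identical(stages(generateHypnogram(480, seed = 5)),
                   stages(generateHypnogram(480, seed = 5)))
  expect_error(generateHypnogram(0), "duration")
  expect_error(generateHypnogram(90.2), "multiple")
})

test_that("stage spectrum templates show the expected landmarks", {
  f <- seq(0.5, 30, 0.5)
  s4 <- stageSpectrumTemplate("S4", f)
  expect_gt(s4[f == 1], s4[f == 20])      # delta dominance in deep sleep
  s2 <- stageSpectrumTemplate("S2", f)
  sp <- f >= 11 & f <= 16
  peak <- f[sp][which.max(s2[sp])]
  expect_gt(min(s2[f == peak] / s2[f == 11], s2[f == peak] / s2[f == 16]), 1)
  rem <- stageSpectrumTemplate("REM", f)
  th <- f >= 4 & f <= 8
  expect_gt(max(rem[th] / (30 / f[th]^1.2 * 0.9)), 1.2)  # theta bump
  expect_true(all(s4 > 0) && all(s2 > 0) && all(rem > 0))
  expect_identical(stageSpectrumTemplate("S2", f),
                   stageSpectrumTemplate("S2", f))
  expect_error(stageSpectrumTemplate("S9"), "stage")
})

test_that("the condition signature multiplies only the configured cells", {
  cfg <- simConfig(nSubjects = 2, signatureAmplitude = 0.2,
                   signatureCells = data.frame(group = 1L, fLo = 11, fHi = 15.5),
                   signatureSegments = 2L, signatureStages = "S2")
  f <- seq(0.5, 30, 0.5)
  base <- matrix(rep(stageSpectrumTemplate("S2", f), each = 4), 4)
  faceM <- embedConditionSignature(base, cfg, "face", "S2", 2L)
  houseM <- embedConditionSignature(base, cfg, "house", "S2", 2L)
  inside <- f >= 11 & f <= 15.5
  expect_equal(faceM[1, inside] / houseM[1, inside],
               rep(1.2 / 0.8, sum(inside)))
  expect_equal(faceM[1, !inside], base[1, !inside])
  expect_equal(faceM[2:4, ], base[2:4, ])          # other groups untouched
  # outside the configured segment or stage nothing changes
  expect_equal(embedConditionSignature(base, cfg, "face", "S2", 1L), base)
  expect_equal(embedConditionSignature(base, cfg, "face", "REM", 2L), base)
  # amplitude zero is the identity
  cfg0 <- simConfig(nSubjects = 2, signatureAmplitude = 0)
  expect_identical(embedConditionSignature(base, cfg0, "face", "S2", 2L), base)
  # negative amplitude is rejected at construction
  expect_error(simConfig(signatureAmplitude = -0.1), "signatureAmplitude")
})

test_that("synthesized signal converges to the stage template spectrum", {
  cfg <- tinySignalConfig()
  hyp <- new("Hypnogram", stages = rep("S4", 20), epochLength = 30,
             lightsOff = 0)
  rec <- synthesizeRecording(hyp, cfg, nChannels = 2, seed = 11)
  tt <- epochAndLabel(rec, hyp)
  ts <- trialSpectra(rec, tt)
  m <- apply(ts@power, c(2, 3), mean)
  tpl <- stageSpectrumTemplate("S4")
  # delta bins within 10 percent relative error after 10 min
  delta <- seq_len(6)
  expect_lt(mean(abs(m[1, delta] / tpl[delta] - 1)), 0.10)
  # spectral fidelity over the whole analysis range
  expect_lt(mean(abs(log(m[1, ] / tpl))), 0.05)
  expect_error(synthesizeRecording(
    new("Hypnogram", stages = character(0), epochLength = 30, lightsOff = 0),
    cfg), "empty")
  rec2 <- synthesizeRecording(hyp, cfg, nChannels = 2, seed = 11)
  expect_identical(rec@signal, rec2@signal)
})

test_that("artefact injection hits the configured rates and bands", {
  cfg <- simConfig(nSubjects = 2, samplingRate = 500, nRawChannels = 4L)
  hyp <- new("Hypnogram", stages = rep("S2", 14), epochLength = 30,
             lightsOff = 0)
  rec <- synthesizeRecording(hyp, cfg, nChannels = 4, seed = 2)
  # all-zero rates leave the recording untouched
  out0 <- injectArtefacts(rec, c(disconnect = 0, jump = 0, muscle = 0))
  expect_identical(out0$recording@signal, rec@signal)
  expect_false(any(out0$mask))
  # jump rate: binomial count over trials
  outJ <- injectArtefacts(rec, c(disconnect = 0, jump = 0.3, muscle = 0),
                          seed = 4)
  nT <- nrow(outJ$mask)
  expect_gt(sum(rowSums(outJ$mask) > 0), qbinom(0.001, nT, 0.3))
  expect_lt(sum(rowSums(outJ$mask) > 0), qbinom(0.999, nT, 0.3))
  # muscle bursts put strong power into 110-140 Hz
  outM <- injectArtefacts(rec, c(disconnect = 0, jump = 0, muscle = 0.3),
                          seed = 5)
  hit <- which(rowSums(outM$mask) > 0)
  expect_gt(length(hit), 0)
  bandPower <- function(sig, tr, ch) {
    ns <- 4 * 500
    x <- sig[ch, ((tr - 1) * ns + 1):(tr * ns)]
    p <- welchPsd(x, 500, fmax = 200)
    fr <- attr(p, "freqs")
    mean(p[fr >= 110 & fr <= 140, 1])
  }
  t1 <- hit[1]
  ch <- which(outM$mask[t1, ])[1]
  clean <- setdiff(seq_len(nrow(outM$mask)), hit)
  cleanMed <- median(vapply(clean[1:20], function(t)
    bandPower(outM$recording@signal, t, ch), 0))
  expect_gt(bandPower(outM$recording@signal, t1, ch), 5 * cleanMed)
})

test_that("behaviour generation respects count bounds and the link slope", {
  set.seed(31)
  cfg0 <- simConfig(nSubjects = 32, behaviourLink = 0, behaviourNoise = 0.3)
  strengths <- setNames(runif(64, 0.2, 1),
                        paste0(rep(sprintf("s%02d", 1:32), each = 2),
                               "_n", rep(1:2, 32)))
  beh <- generateBehaviour(cfg0, strengths, seed = 9)
  expect_true(all(beh$hits >= 0 & beh$hits <= beh$nOld))
  expect_true(all(beh$falseAlarms >= 0 & beh$falseAlarms <= beh$nNew))
  sc <- scoreBehaviour(beh)
  r0 <- spearmanRho(strengths[sc$nightId], sc$consolidation)
  expect_lt(abs(r0$rho), 0.3)             # no link, n = 64
  # strong link at low noise: large item counts isolate the link from
  # binomial counting noise, which otherwise caps the correlation
  cfgL <- simConfig(nSubjects = 32, behaviourLink = 4, behaviourNoise = 0.02,
                    nOld = 1000L, nNew = 500L)
  behL <- generateBehaviour(cfgL, strengths, seed = 9)
  scL <- scoreBehaviour(behL)
  rL <- spearmanRho(strengths[scL$nightId], scL$consolidation)
  expect_gt(rL$rho, 0.8)
})

test_that("cohorts are counterbalanced, reproducible and level-consistent", {
  coh <- cellsCohort()
  tab <- table(coh@nights$subjectId, coh@nights$condition)
  expect_true(all(tab == 1))
  coh2 <- simulateCohort(coh@config, level = "cells")
  expect_equal(coh@cellMeans, coh2@cellMeans)
  expect_equal(coh@behaviour, coh2@behaviour)
  # trials-level: signature cells carry the condition ratio
  cfg <- simConfig(nSubjects = 4, signatureAmplitude = 0.4,
                   amplitudeGainSd = 0, trialStride = 8L, seed = 3)
  coh3 <- simulateCohort(cfg, level = "trials")
  f <- seq(0.5, 30, 0.5)
  sb <- f >= 11 & f <= 15.5
  vals <- vapply(coh3@nights$nightId, function(nid) {
    ts <- coh3@spectra[[nid]]
    sel <- ts@stage %in% c("S2", "S3", "S4") & !is.na(ts@segment) &
      ts@segment == 2
    mean(ts@power[sel, 7, sb])
  }, 0)
  byCond <- tapply(vals, coh3@nights$condition, mean)
  expect_gt(byCond[["face"]] / byCond[["house"]], 1.5)  # 1.4/0.6 = 2.33
})
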