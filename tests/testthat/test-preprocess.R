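# Feature preparation: epoching, artefact screening, Welch estimation,
# spatial averaging, per-cell aggregation, normalization and sharpening.

test_that("trials tile 30-s epochs and inherit onset-based segments", {
  hyp <- generateHypnogram(480, seed = 1)
  tt <- somnidec:::hypnogramTrialTable(hyp)
  expect_equal(nrow(tt), 960 * 7)          # 7 whole 4-s trials per epoch
  expect_equal(sum(tt$onset < 30), 7)
  expect_true(all(diff(tt$onset) > 0))
  # onset rule at the segment boundary: 89.9 min is still segment 1
  expect_equal(tt$segment[which.max(tt$onset[tt$onset < 90 * 60])], 1L)
  expect_equal(tt$segment[tt$onset == 90 * 60][1], 2L)
  # a 480-min night has exactly segments 1..5; the 30-min remainder is NA
  expect_equal(sort(unique(tt$segment[!is.na(tt$segment)])), 1:5)
  expect_true(all(is.na(tt$segment[tt$onset >= 450 * 60])))
  expect_identical(tt$stage, rep(stages(hyp), each = 7))
})

test_that("Welch estimation has 0.5 Hz bins and matches a DFT oracle", {
  fs <- 250
  t <- seq(0, 4 - 1 / fs, by = 1 / fs)
  p <- welchPsd(sin(2 * pi * 10 * t), fs)
  freqs <- attr(p, "freqs")
  expect_equal(nrow(p), 60)
  expect_equal(freqs, seq(0.5, 30, 0.5))
  expect_equal(diff(freqs)[1], 0.5)
  expect_equal(freqs[which.max(p)], 10)
  # oracle: direct rectangular-window DFT of one 2-s segment localizes
  # the same frequency
  seg <- sin(2 * pi * 10 * t[1:500])
  dft <- Mod(fft(seg))^2
  fg <- (0:499) * fs / 500
  expect_equal(fg[which.max(dft[1:250])], 10)
  # white noise is flat after averaging many trials
  set.seed(2)
  acc <- 0
  for (i in 1:100) acc <- acc + welchPsd(rnorm(1000), fs)
  expect_lt(max(acc) / min(acc), 2)
  # total power is conserved: integral of the PSD approximates the
  # variance (white noise, flat to Nyquist)
  set.seed(3)
  x <- rnorm(10000)
  pw <- welchPsd(x, fs, fmax = 125)
  expect_equal(sum(pw) * 0.5, var(x), tolerance = 0.1)
  expect_error(welchPsd(rnorm(100), fs), "window")
  expect_error(welchPsd(rnorm(1000), fs, overlap = 1), "overlap")
})

test_that("artefact screening recovers injected artefacts", {
  cfg <- simConfig(nSubjects = 2, samplingRate = 500, nRawChannels = 8L)
  hyp <- new("Hypnogram", stages = rep(c("S2", "S3"), 10), epochLength = 30,
             lightsOff = 0)
  rec <- synthesizeRecording(hyp, cfg, nChannels = 8, seed = 3)
  tt <- epochAndLabel(rec, hyp)
  # clean recording: almost nothing is flagged
  det0 <- detectArtefacts(rec, tt)
  expect_lt(mean(det0$mask), 0.01)
  expect_length(det0$badChannels, 0)
  # a dead channel is caught whole
  inj <- injectArtefacts(rec, c(disconnect = 0.99, jump = 0, muscle = 0),
                         seed = 1)
  injOne <- rec
  injOne@signal[3, ] <- inj$recording@signal[3, ]
  det1 <- detectArtefacts(injOne, tt)
  expect_true(3 %in% det1$badChannels)
  # muscle bursts are recovered with high sensitivity
  injM <- injectArtefacts(rec, c(disconnect = 0, jump = 0, muscle = 0.1),
                          seed = 2)
  detM <- detectArtefacts(injM$recording, tt)
  truth <- injM$mask
  sens <- sum(detM$mask & truth) / sum(truth)
  expect_gt(sens, 0.9)
  # low sampling rate: muscle criterion skipped with a warning
  expect_warning(detectArtefacts(
    synthesizeRecording(hyp, simConfig(nSubjects = 2, samplingRate = 250),
                        nChannels = 2, seed = 4), tt),
    "muscle")
})

test_that("bad-channel interpolation is a weighted neighbour average", {
  montage <- makeSyntheticMontage(32)
  sig <- matrix(rep(sin(seq(0, 10, length.out = 500)), each = 32), 32,
                byrow = FALSE)
  rec <- new("EEGRecording", signal = sig, samplingRate = 125,
             channelNames = montage$electrodes$name[1:32],
             subjectId = "s", night = 1L, condition = NA_character_)
  # all neighbours identical -> reconstruction equals that signal
  mSub <- makeSyntheticMontage(32)
  out <- interpolateBadChannels(rec, 5L, mSub)
  expect_equal(out$recording@signal[5, ], sig[6, ], tolerance = 1e-9)
  # no bad channels -> identity
  out0 <- interpolateBadChannels(rec, integer(0), mSub)
  expect_identical(out0$recording@signal, rec@signal)
  # interpolated variance never exceeds the largest neighbour variance
  set.seed(9)
  rec2 <- rec
  rec2@signal <- matrix(rnorm(32 * 500), 32)
  out2 <- interpolateBadChannels(rec2, 5L, mSub)
  D <- somnidec:::electrodeDistances(mSub)
  nb <- setdiff(which(D[5, ] <= 2 * mSub$groupRadius), 5L)
  expect_lte(var(out2$recording@signal[5, ]),
             max(apply(rec2@signal[nb, ], 1, var)))
})

test_that("spatial averaging reduces electrodes to 32 groups correctly", {
  montage <- makeSyntheticMontage(64)
  nT <- 3; nCh <- 64; nB <- 60
  pow <- array(1, c(nT, nCh, nB))
  ts <- new("TrialSpectra", power = pow, freqs = seq(0.5, 30, 0.5),
            onset = (0:2) * 4, stage = rep("S2", 3),
            segment = rep(1L, 3), mask = matrix(FALSE, nT, nCh),
            channelNames = montage$electrodes$name)
  g <- spatialAverage(ts, montage)
  expect_equal(dim(g@power)[2], 32)
  expect_true(all(g@power == 1))           # identical members -> same value
  # doubling one member shifts the group mean by increment / group size
  mem <- montage$membership[[1]]
  ts2 <- ts
  ts2@power[, mem[1], ] <- 2
  g2 <- spatialAverage(ts2, montage)
  expect_equal(g2@power[1, 1, 1], 1 + 1 / length(mem))
})

test_that("cell aggregation honours the 40-trial inclusion criterion", {
  nB <- 60
  mk <- function(n) {
    new("TrialSpectra",
        power = array(rep(c(0.2, 0.4), each = n / 2), c(n, 1, nB)),
        freqs = seq(0.5, 30, 0.5), onset = (seq_len(n) - 1) * 4,
        stage = rep("S2", n), segment = rep(1L, n),
        mask = matrix(FALSE, n, 1), channelNames = "G1")
  }
  expect_null(aggregateCell(mk(39), "S2", 1))          # 39 trials excluded
  m40 <- aggregateCell(mk(40), "S2", 1)
  expect_equal(attr(m40, "nTrials"), 40)
  expect_equal(unname(m40[1, 1]), 0.3)                 # mean of 0.2 and 0.4
  same <- mk(40)
  same@power[] <- 0.7
  expect_true(all(aggregateCell(same, "S2", 1) == 0.7))
  # SWS pooling: S3+S4 by default, S4 only in "s4" mode
  sws <- mk(80)
  sws@stage <- rep(c("S3", "S4"), 40)
  expect_equal(attr(aggregateCell(sws, "SWS", 1), "nTrials"), 80)
  expect_equal(attr(aggregateCell(sws, "SWS", 1, swsMode = "s4"), "nTrials"),
               40)
})

test_that("normalization maps each channel onto [0, 1]", {
  m <- rbind(c(2, 4, 6), c(1, 1, 1))
  expect_warning(nm <- normalizeChannels(m), "constant")
  expect_equal(nm[1, ], c(0, 0.5, 1))
  expect_equal(nm[2, ], c(0, 0, 0))
  set.seed(4)
  x <- matrix(rnorm(5 * 60), 5)
  nx <- normalizeChannels(x)
  expect_equal(unname(apply(nx, 1, min)), rep(0, 5))
  expect_equal(unname(apply(nx, 1, max)), rep(1, 5))
  # scale invariance
  expect_equal(normalizeChannels(10 * x), nx)
})

test_that("the sharpening filter removes smooth baselines exactly", {
  expect_equal(sharpenSpectrum(matrix(5, 1, 20)), matrix(0, 1, 20))
  # interior of a linear ramp cancels (symmetric neighbour window)
  ramp <- matrix(seq_len(20), 1)
  sh <- sharpenSpectrum(ramp)
  expect_equal(sh[1, 4:17], rep(0, 14))
  # a unit spike: centre keeps its full height, neighbours dip by 1/6
  spike <- matrix(0, 1, 21)
  spike[1, 11] <- 1
  shs <- sharpenSpectrum(spike)
  expect_equal(shs[1, 11], 1)
  expect_equal(shs[1, 10], -1 / 6)
  expect_equal(shs[1, 12], -1 / 6)
  expect_error(sharpenSpectrum(matrix(1, 1, 5)), "bins")
})

test_that("the preparation order normalize-then-sharpen is not commutative", {
  set.seed(11)
  m <- matrix(abs(rnorm(2 * 60, 10, 3)), 2)
  a <- sharpenSpectrum(normalizeChannels(m))
  b <- normalizeChannels(sharpenSpectrum(m))
  expect_gt(max(abs(a - b)), 0.01)
  # and prepareFeatures uses the pipeline order
  expect_equal(somnidec:::prepareFeatures(m), a)
})

test_that("feature containers have the 32 x 60 shape and paired subjects", {
  coh <- cellsCohort()
  se <- buildCellFeatures(coh, "SWS", 2, minTrials = 40, minSubjects = 11)
  expect_equal(S4Vectors::metadata(se)$nGroups, 32)
  expect_equal(S4Vectors::metadata(se)$nBins, 60)
  expect_equal(nrow(se), 32 * 60)
  cd <- SummarizedExperiment::colData(se)
  expect_true(all(table(cd$subjectId) == 2))
  expect_true(all(cd$nTrials >= 40))
  # every included subject contributes exactly one feature vector per night
  expect_equal(ncol(se), 2 * length(unique(cd$subjectId)))
  # a too-strict subject minimum excludes the cell entirely
  expect_null(buildCellFeatures(coh, "SWS", 2, minSubjects = 99))
})
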