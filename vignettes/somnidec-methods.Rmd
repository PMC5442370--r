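---
title: "Decoding learned stimulus category from sleep-EEG spectra: models and methods"
author: "somnidec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding learned stimulus category from sleep-EEG spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The analysis problem

After a subject spends an evening intensively studying either faces or
houses and then sleeps, does the continuous sleep EEG carry a decodable
trace of *what* was learned?  somnidec implements the complete analysis
pipeline for this question: spectral feature preparation from overnight
high-density EEG, a two-step between-subject linear classifier with
label-permutation inference, a sliding-window time course of decoding
accuracy, and the statistics that relate per-subject decoding strength to
overnight recognition-memory consolidation.  Because all-night human
recordings for this design are not publicly available, the package pairs
the analysis with a synthetic cohort generator whose ground truth is
known exactly, so every stage is verifiable end to end.

## Feature preparation

Each night is scored in 30-s epochs (stages W, S1, S2, S3, S4, REM, MT;
S3+S4 are pooled as slow-wave sleep, SWS).  The pipeline is, in fixed
order:

1. **Epoching.** The recording is cut into non-overlapping 4-s trials
   tiled inside each 30-s epoch (7 whole trials per epoch, the 2-s
   remainder dropped).  A trial inherits its epoch's stage and the
   90-min segment of its onset, counted from lights off; only full
   segments exist (a 480-min night has segments 1--5).
2. **Artefact screening.** Three per-trial, per-channel statistics --
   overall log spectral power, maximal sample-to-sample amplitude
   change, and 110--140 Hz band power -- are screened automatically at
   median +/- k MAD (k = 5 by default; the original procedure was
   semiautomatic with visual confirmation, which an unattended pipeline
   cannot reproduce).  Channels flagged in more than 20 percent of trials
   are rejected whole and rebuilt by inverse-distance-weighted
   interpolation of good electrodes within twice the grouping radius.
   The muscle criterion needs a sampling rate of at least 280 Hz and is
   skipped (with a warning) below that.
3. **Welch spectra.** Each trial's power spectral density is the mean of
   Hamming-windowed periodograms over 2-s windows at 95 percent overlap.
   A 2-s window fixes the resolution at 0.5 Hz regardless of sampling
   rate; bins at 0.5, 1.0, ..., 30 Hz are kept (60 bins).  Note that
   a 4-s trial yields 21 such windows; we fix the window length and
   overlap and let the window count follow, since the 0.5 Hz resolution
   is what the downstream feature shape depends on.
4. **Spatial averaging.** Electrode spectra are averaged within a
   radius of about 3 cm (on a 9.5-cm spherical head model) around the 32
   evenly spread extended 10--20 locations, reducing 128 channels to 32
   groups.  The shipped montage is synthetic -- 32 centre positions from
   10--20 arc geometry plus a Fibonacci-spiral electrode cap -- and
   replaceable by any table of positions.
5. **Per-cell averaging.** Trial spectra are averaged over all
   artefact-free trials of one analysis cell (sleep stage x 90-min
   segment).  A subject-night enters a cell only with at least 40 clean
   trials (160 s of data); a cell is analysed only when at least 11
   subjects qualify with both nights.
6. **Normalization.** Each channel's 60-bin spectrum is mapped to
   [0, 1].  This removes reference-distance amplitude differences
   between channels and global power differences between subjects.
7. **Spectral sharpening.** From every bin the mean of its six
   neighbouring bins (three per side, centre excluded, truncated at the
   edges) is subtracted.  "Six neighbouring bins" is read as symmetric
   exclusion of the centre -- the only reading that gives exactly six.
   Sharpening removes the smooth 1/f baseline and accentuates
   narrow-band deviations; outputs may be negative.

Steps 6 and 7 do not commute and their order is asserted by a test.
The result is one 32 x 60 feature matrix per subject-night per cell.

## The two-step classifier

Training and validation subjects are strictly separated, with both
nights of a subject always on the same side of every split.

* **Inner loop (channel weights).** For each of the 32 channel groups, a
  linear soft-margin SVM (cost C = 1 by default; the original toolchain's
  default) is trained on that channel's 60 bins over all but one training
  subject and evaluated on the held-out subject's two nights,
  leave-one-subject-out across the training set.  The mean held-out
  accuracy of a channel becomes its weight.  Weights are raw accuracies,
  not chance-subtracted, matching the procedure's description.
* **Outer step.** The 32 channels are combined into one 60-bin vector
  per night by the accuracy-weighted average, the main linear SVM is
  trained on the weighted training vectors, and accuracy is measured on
  the held-out validation subjects.  Probability estimates come from a
  Platt-type logistic calibration fitted on training decision values
  only (with the usual smoothed targets, so separable folds keep a
  finite slope).
* **Cross-validation.** The whole procedure is repeated over random
  subject-level 5-fold partitions (280 repetitions at full scale; fold
  sizes differ by at most one subject).  Per-night probability estimates
  are averaged over repetitions.  Decision-value ties (exactly zero) are
  deterministically assigned to the face class.

The SVM solver is an SMO implementation of the standard C-SVC dual with
an unregularized bias, written in C++ for speed: a permutation run
re-fits on the order of 10^5 small SVMs, which rules out per-call
overhead of generic libraries.  The solver is deterministic
(maximal-violating-pair selection) and is verified in the test suite
against libsvm (e1071), against a box-constrained QP solution of the
same dual (kernlab::ipop), and against an explicit grid-search
brute-force implementation of the entire two-step procedure.
A bias-*regularized* formulation (augmented constant feature) is not
equivalent here: when features carry a common offset and the data are
far from separable, its optimum can leave the intercept at zero and
classify at chance, which we observed and rejected.

## Inference

Significance is assessed exclusively by label permutation: per subject,
the two night labels are swapped with probability 1/2 (identity
permutations allowed), the complete pipeline including the inner loop is
re-run, and p is the fraction of null accuracies at or above the
observed one.  With no null draw reaching it, p is reported as a bound
p < 1/nPerm (1/1001 ~ 0.001 at full scale).  Per-permutation
repetitions are reduced (5 by default) to keep 1,001 permutations
tractable; the observed statistic is computed at the same reduced
setting so observed and null remain exchangeable.  Families of cell
p-values are Holm-corrected.

The time course of decodability uses a 22.5-min window sliding in
4.5-min steps; within each window, a night's trials of the target stage
are aggregated, normalized and sharpened exactly as in the main
analysis.  The per-window trial minimum is not specified by the design
the package emulates; we default to 8 trials (the 40-trial criterion
scaled by the roughly five-fold shorter data span), exposed as a
parameter.  Windows failing inclusion are missing, not zero.

## Behaviour

Recognition performance is d' = z(hit rate) - z(false-alarm rate) with
the log-linear correction (count + 0.5)/(n + 1), so perfect scores stay
finite; overnight consolidation is post- minus pre-sleep d'.
Reprocessing strength of a night is its mean calibrated probability of
the true condition.  The package reports Spearman correlations (p from
the t approximation), partial Spearman correlations (rank-transform,
then partial Pearson), an OLS regression on standardized predictors with
per-predictor variance explained as the squared semipartial correlation
(the drop in R^2 when the predictor is removed), a stage x strength
slope-interaction test on stacked observations with cluster-robust
(by subject) standard errors -- the pairing of the two stage strengths
within a subject makes plain OLS errors invalid -- and a sensitivity
re-analysis after removing the k = 3 highest-leverage observations of
the simple regression.

## The synthetic cohort generator

The generator is a verification instrument: it produces data with the
statistical structure the analysis assumes and known ground truth, not a
biophysical simulation.  Its components:

* **Hypnograms**: a cyclic stage template (W -> S1 -> S2 -> S3 -> S4 ->
  re-ascent -> REM) with 90-min period, jittered stage durations, SWS
  shrinking and REM growing across the night.  Every full 90-min
  segment contains S2, SWS and REM.
* **Spectra**: stage templates are a 1/f^1.2 baseline plus landmarks --
  a delta peak in S3/S4, a ~13 Hz spindle peak in S2 and SWS, a ~6 Hz
  theta bump in REM, alpha in wake.  Spindle-peak heights (25, 35, 30
  uV^2/Hz in S2, S3, S4) are chosen so that after zero-one
  normalization the spindle landmark is a visible fraction (~0.1--0.4)
  of each stage's spectral range; with a spindle peak buried below a few
  percent of the delta peak, no linear classifier can use it after
  normalization, and the generator would be unable to represent a
  decodable signature at all.
* **Condition signature**: power in configured (channel group x
  frequency band) cells is multiplied by 1 + s * amplitude (s = +1 for
  face, -1 for house) within configured stages and 90-min segments.
  The default places amplitude 0.5 on one group in the spindle band
  during segment 2 of S2/SWS sleep.  Realized per-night strength is
  trait-like: a subject-level log-normal gain (80 percent of the
  variance) plus a night-level gain.
* **Between-subject variability** is modelled as primarily *regional*:
  each (subject, group) draws a smooth 1/f-tilt of the spectrum
  (exponent sd 0.02) and per-band log-normal gains (sd 0.015), on top
  of a small globally shared band gain (sd 0.005).  This choice is
  deliberate and load-bearing.  A band-uniform gain that is *shared*
  across channels is statistically confounded with a band-confined
  signature under the accuracy-weighted channel average: averaging
  cannot reduce it, and with a single informative group the weighted
  average dilutes the signature by a factor of about w_sig / sum(w)
  ~ 1/16, so even modest shared band variance pins the outer classifier
  near chance regardless of how cleanly single channels separate.
  Regional variability, by contrast, both challenges the per-channel
  classifiers and is attenuated by spatial averaging -- which is exactly
  the signal-to-noise logic the preprocessing chain embodies.  Smooth
  tilts are additionally the component the sharpening filter is designed
  to remove.
* **Single-trial noise** is multiplicative log-normal per (trial, group,
  bin) with sd 0.5, the approximate relative error of a single 4-s
  Welch estimate at these settings.
* **Artefacts**: whole-channel disconnection (flat or noise-dominated),
  within-trial step discontinuities, and 110--140 Hz bursts, each at a
  configurable rate, with a ground-truth mask returned for detector
  validation.
* **Behaviour**: pre-sleep d' ~ N(1.7, 0.3); target consolidation =
  intercept + link x realized strength + N(0, 0.15); hit and
  false-alarm counts are binomial draws (100 old / 50 new items, an
  unbiased criterion), so count bounds hold by construction.  The
  default link slope is 3 in d' units per unit realized amplitude.

Three fidelity levels trade physics for compute.  `"signal"` emits raw
multichannel time series (per 30-s epoch, amplitude-fixed random-phase
noise shaped to the stage template, 0.5-s crossfades at joins) and
exercises the full Welch/artefact path.  `"trials"` emits per-trial
group-level spectra directly and supports the sliding-window analysis.
`"cells"` samples per-cell mean spectra with the noise scale of a mean
over the cell's trial count and is used for the statistical suites
(hundreds of cohorts).  The phase-randomized synthesis realizes the
target spectrum exactly per epoch, so the Welch estimate of 10 min of a
single stage deviates from the template by under 0.05 mean absolute log
units; most of the residual is Hamming-window leakage around the sharp
spectral peaks, which is why convergence at 5 min can still sit
marginally above that bound.

## Problem sizes and reproducibility

All randomness flows from one master seed through deterministic
counter-based splitting, so cohorts, fold assignments and permutations
are bitwise reproducible, and identical configurations yield identical
results.  The test and acceptance suites run at the following sizes,
chosen as the package's own verification design: study-sized cohorts
(32 subjects, 64 nights) for signature recovery and behaviour coupling;
12-subject cohorts with 8 channel groups, 99 permutations and 200
replicate cohorts for the type-I-error calibration of the permutation
test (the exchangeability argument is dimension-free, so reduced
dimensionality changes nothing about the property under test); and a
6-subject, 2-channel, 3-bin toy cohort for exact equivalence with the
brute-force oracle.  Trial thinning (`trialStride`) reduces memory for
trial-level cohorts; the sliding-window analyses use stride 4 (one 4-s
trial per 16 s), which leaves every window's trial counts far above the
inclusion minimum.

## What passing tests do and do not show

The generator reproduces the *statistical* structure the analysis
assumes: stage-dependent spectra, paired counterbalanced nights, a
multiplicative band-confined signature, trait-like strength
heterogeneity, behaviour coupled to strength.  It does not model
cortical sources, volume conduction, K-complexes or eye movements,
stage-transition dynamics beyond the cyclic template, or non-stationary
artefact morphology.  Recovery results therefore validate the pipeline's
correctness and calibration -- not the claim that real sleep EEG carries
such signatures, which only the original recordings could support.
Known limitations: the null distribution of Spearman correlations at 64
nights has standard deviation ~0.126, so the "null stage" correlations
scatter accordingly; with thresholds of |rho| < 0.2 per stage, joint
null checks across two stages pass in roughly 80--85 percent of cohorts
by that arithmetic alone.

## Key defaults

| Parameter | Default | Meaning |
|---|---|---|
| `trialLen` | 4 s | analysis trial length |
| `k` (MAD) | 5 | artefact outlier threshold |
| `minTrials` | 40 | per-cell inclusion (160 s) |
| `minSubjects` | 11 | per-cell subject minimum |
| `cost` | 1 | SVM cost C |
| `reps` | 280 (full) / 20 | k-fold repetitions |
| `folds` | 5 | cross-validation folds |
| `nPerm` | 1001 (full) / 99 | permutations |
| `windowWidth`, `windowStep` | 22.5, 4.5 min | time-course geometry |
| `signatureAmplitude` | 0.5 | condition effect size |
| `behaviourLink` | 3 | d' per unit realized strength |
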