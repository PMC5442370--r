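# somnidec

Decoding previously learned stimulus category (faces vs. houses) from
continuous sleep-EEG power spectra.

## The problem and who this is for

In category-learning sleep studies, a subject studies one class of
images (faces or houses) in the evening and sleeps under high-density
EEG; each subject contributes two counterbalanced nights, one per
category. The scientific question is whether the continuous sleep EEG
carries a decodable trace of the learned category — spontaneous memory
reprocessing — and whether its strength predicts overnight
consolidation of recognition memory. somnidec is for sleep/EEG
methodologists who want this full analysis as tested, reproducible R
code, together with a synthetic cohort generator (known ground truth)
for validating every stage.

## The method

Per night, the EEG is cut into 4-s trials (stage-labelled from a 30-s
hypnogram), artefact-screened (median ± 5·MAD on overall power,
amplitude jumps, and 110–140 Hz muscle power), and transformed to Welch
power spectra (2-s Hamming windows, 95 % overlap → 0.5 Hz bins,
0.5–30 Hz). Spectra are averaged onto the 32 extended 10–20 channel
groups (~3 cm radius), averaged over the artefact-free trials of each
analysis cell (sleep stage × 90-min segment; ≥ 40 trials per night,
≥ 11 subjects per cell), normalized to [0, 1] per channel, and passed
through a spectral sharpening filter (subtract the mean of the six
neighbouring bins), giving one 32 × 60 feature matrix per subject-night.

Decoding is between-subject and two-step: per channel, a linear SVM's
leave-one-subject-out accuracy becomes that channel's weight; the main
linear SVM is trained on the accuracy-weighted channel average and
evaluated on held-out subjects, over repeated subject-level 5-fold
partitions (both nights of a subject always travel together).
Significance comes from per-subject label-swap permutations (full
pipeline re-run per permutation; p = #{null ≥ observed}/nPerm, floor
1/1001 at full scale) with Holm correction across cells. A 22.5-min
window sliding in 4.5-min steps gives the time course of decodability.
Behaviour is scored as d′ = z(hits) − z(false alarms) (log-linear
correction); consolidation (post − pre d′) is related to per-night
decoding strength via Spearman and partial correlations, standardized
OLS with squared-semipartial variance decomposition, a cluster-robust
stage × strength interaction test, and a leverage-based sensitivity
filter.

## Worked example

```r
library(somnidec)

# a synthetic study-sized cohort: 32 subjects x 2 nights, a spindle-band
# signature of amplitude 0.3 in channel group 7 during segment 2 of
# S2/SWS sleep
cfg <- simConfig(nSubjects = 32, signatureAmplitude = 0.3,
                 amplitudeGainSd = 0, seed = 1)
coh <- simulateCohort(cfg, level = "cells")

se  <- buildCellFeatures(coh, stage = "SWS", segment = 2)
res <- crossValidatedDecode(se, reps = 20, folds = 5, seed = 1)
res
#> DecodingResult [SWS, segment 2]: validation 0.900, training 0.939
#>    32 subjects, 20 reps x 5 folds, C = 1

maps <- featureWeightMaps(res)
which.max(maps$topography[, "spindle"])   # 7  — the seeded group
nd <- permutationTest(se, nPerm = 99, reps = 5, seed = 1)
nd
#> NullDistribution: observed 0.909, p < 0.0101 (99 permutations)
```

The validation accuracy (0.900) is the fraction of held-out
subject-nights whose learned category the classifier identifies; the
permutation p-value says no label-swapped null run reached it. The
spindle-band topography maximum recovers the channel group that
actually carried the simulated signature.

`runPipeline(runConfig(...))` chains simulation, feature preparation,
decoding of all cells, permutation inference with Holm correction, the
sliding-window time course and the behaviour statistics, and writes
JSON/TSV summaries.

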