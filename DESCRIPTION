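Package: somnidec
Title: Decoding Learned Stimulus Category from Continuous Sleep-EEG Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to decode a previously learned stimulus category (faces
    versus houses) from continuous sleep-EEG power spectra. Implements the
    full analysis path: spectral feature preparation (4-s trial epoching,
    median/MAD artefact rejection, Welch power spectral density with 2-s
    Hamming windows at 95% overlap, spatial averaging onto 32 extended
    10-20 channel groups, per-cell trial averaging, zero-one normalization
    and a spectral sharpening filter), a two-step between-subject linear
    support-vector classifier with accuracy-weighted channel averaging and
    repeated subject-level 5-fold cross-validation, label-permutation
    significance testing with Holm correction, a sliding-window time course
    of decoding accuracy across the night, and recognition-memory statistics
    (d-prime, overnight consolidation, Spearman and partial correlations,
    standardized regression with variance decomposition, slope-interaction
    and leverage diagnostics). A synthetic sleep-EEG cohort generator with
    known ground truth (stage-dependent 1/f spectra, 90-min cycle
    hypnograms, condition-specific spectral signatures, artefact injection,
    coupled behaviour) makes every stage verifiable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    jsonlite,
    signal,
    sandwich,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    e1071,
    kernlab
Config/testthat/edition: 3
RoxygenNote: 7.3.3
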