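# File formats at the package boundary: hypnogram TSV (onset_s <TAB>
# stage), behaviour CSV, classic EDF for raw recordings, and JSON for
# result summaries.  The EDF reader/writer implements the original
# 16-bit continuous-recording variant of the format.

#' Read a hypnogram TSV
#'
#' Expects a header line \code{onset_s<TAB>stage} and one row per 30-s
#' epoch with onsets increasing in steps of the epoch length.
#'
#' @param path file path
#' @param epochLength epoch length in seconds (default 30)
#' @return A \linkS4class{Hypnogram}.
#' @export
readHypnogram <- function(path, epochLength = 30) {
  tab <- tryCatch(read.delim(path, stringsAsFactors = FALSE),
                  error = function(e) stop("cannot parse ", path, ": ",
                                           conditionMessage(e)))
  if (!nrow(tab)) stop("empty hypnogram file: ", path)
  if (!all(c("onset_s", "stage") %in% names(tab)))
    stop("hypnogram needs columns onset_s and stage")
  bad <- which(!tab$stage %in% STAGE_LEVELS)
  if (length(bad))
    stop("unknown stage token '", tab$stage[bad[1]], "' at line ",
         bad[1] + 1L, " of ", path)
  expected <- (seq_len(nrow(tab)) - 1) * epochLength
  if (any(abs(tab$onset_s - expected) > 1e-6))
    stop("onsets must increase in steps of ", epochLength, " s")
  new("Hypnogram", stages = tab$stage, epochLength = epochLength,
      lightsOff = 0)
}

#' Write a hypnogram TSV
#'
#' @param hypnogram a \linkS4class{Hypnogram}
#' @param path output path
#' @return the path, invisibly
#' @export
writeHypnogram <- function(hypnogram, path) {
  tab <- data.frame(onset_s = (seq_along(stages(hypnogram)) - 1) *
                      hypnogram@epochLength,
                    stage = stages(hypnogram))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write behaviour tables
#'
#' CSV with columns subject, night, session, n_old, n_new, hits,
#' false_alarms (one row per night x session).
#'
#' @param path file path
#' @return data.frame in the package's internal column naming
#' @export
readBehaviour <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject", "night", "session", "n_old", "n_new", "hits",
            "false_alarms")
  if (!all(need %in% names(tab)))
    stop("behaviour CSV needs columns ", paste(need, collapse = ", "))
  data.frame(subjectId = tab$subject, night = as.integer(tab$night),
             session = tab$session, nOld = as.integer(tab$n_old),
             nNew = as.integer(tab$n_new), hits = as.integer(tab$hits),
             falseAlarms = as.integer(tab$false_alarms))
}

#' @rdname readBehaviour
#' @param behaviour internal-format behaviour data.frame
#' @export
writeBehaviour <- function(behaviour, path) {
  out <- data.frame(subject = behaviour$subjectId, night = behaviour$night,
                    session = behaviour$session, n_old = behaviour$nOld,
                    n_new = behaviour$nNew, hits = behaviour$hits,
                    false_alarms = behaviour$falseAlarms)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# fixed-width ASCII field for EDF headers
edfField <- function(x, width) {
  s <- as.character(x)
  if (nchar(s) > width) s <- substr(s, 1, width)
  formatC(s, width = -width)
}

edfNum <- function(x, width = 8) {
  s <- formatC(x, digits = 6, format = "g")
  if (nchar(s) > width) s <- substr(s, 1, width)
  formatC(s, width = -width)
}

#' Write a recording as classic EDF
#'
#' One-second data records, 16-bit little-endian samples, symmetric
#' physical scaling per channel.  The sampling rate must be an integer;
#' trailing samples not filling a whole record are dropped.
#'
#' @param recording an \linkS4class{EEGRecording}
#' @param path output path
#' @return the path, invisibly
#' @export
writeEdf <- function(recording, path) {
  fs <- recording@samplingRate
  if (abs(fs - round(fs)) > 1e-9) stop("EDF export needs an integer sampling rate")
  fs <- as.integer(round(fs))
  sig <- recording@signal
  nCh <- nrow(sig)
  nRec <- floor(ncol(sig) / fs)
  sig <- sig[, seq_len(nRec * fs), drop = FALSE]
  physMax <- pmax(apply(abs(sig), 1, max), 1e-6)
  con <- file(path, "wb")
  on.exit(close(con))
  hdrBytes <- 256L + 256L * nCh
  patient <- edfField(recording@subjectId, 80)
  recInfo <- edfField(sprintf("night %d condition %s", recording@night,
                              recording@condition), 80)
  writeChar(paste0(edfField("0", 8), patient, recInfo,
                   edfField("01.01.00", 8), edfField("00.00.00", 8),
                   edfField(hdrBytes, 8), edfField("", 44),
                   edfField(nRec, 8), edfField(1, 8), edfField(nCh, 4)),
            con, eos = NULL)
  wf <- function(vals, width) writeChar(
    paste(vapply(vals, edfField, "", width = width), collapse = ""),
    con, eos = NULL)
  wf(recording@channelNames, 16)
  wf(rep("", nCh), 80)                       # transducer
  wf(rep("uV", nCh), 8)                      # physical dimension
  writeChar(paste(vapply(-physMax, edfNum, ""), collapse = ""), con,
            eos = NULL)
  writeChar(paste(vapply(physMax, edfNum, ""), collapse = ""), con,
            eos = NULL)
  wf(rep(-32767L, nCh), 8)
  wf(rep(32767L, nCh), 8)
  wf(rep("", nCh), 80)                       # prefiltering
  wf(rep(fs, nCh), 8)
  wf(rep("", nCh), 32)
  gain <- physMax / 32767
  for (r in seq_len(nRec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    block <- round(sig[, idx, drop = FALSE] / gain)
    block[block > 32767] <- 32767
    block[block < -32767] <- -32767
    writeBin(as.integer(t(block)), con, size = 2L, endian = "little")
  }
  invisible(path)
}

#' Read a classic EDF file
#'
#' @param path file path
#' @return An \linkS4class{EEGRecording}; subject/night/condition are
#'   recovered from the header fields written by \code{\link{writeEdf}}
#'   when present.
#' @export
readEdf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  version <- rd(8)
  patient <- rd(80)
  recInfo <- rd(80)
  rd(8); rd(8); rd(8); rd(44)
  nRec <- as.integer(rd(8))
  recDur <- as.numeric(rd(8))
  nCh <- as.integer(rd(4))
  rdv <- function(w) vapply(seq_len(nCh), function(i) rd(w), "")
  labels <- rdv(16)
  rdv(80)
  rdv(8)
  physMin <- as.numeric(rdv(8))
  physMax <- as.numeric(rdv(8))
  digMin <- as.numeric(rdv(8))
  digMax <- as.numeric(rdv(8))
  rdv(80)
  spr <- as.integer(rdv(8))
  rdv(32)
  if (length(unique(spr)) != 1L)
    stop("mixed per-channel sampling rates are not supported")
  fs <- spr[1] / recDur
  sig <- matrix(0, nCh, nRec * spr[1])
  for (r in seq_len(nRec)) {
    raw <- readBin(con, "integer", n = nCh * spr[1], size = 2L,
                   signed = TRUE, endian = "little")
    block <- matrix(raw, nrow = spr[1])
    idx <- ((r - 1L) * spr[1] + 1L):(r * spr[1])
    sig[, idx] <- t(block)
  }
  gain <- (physMax - physMin) / (digMax - digMin)
  sig <- sig * gain + (physMax - gain * digMax)
  rownames(sig) <- labels
  night <- 1L
  condition <- NA_character_
  m <- regmatches(recInfo,
                  regexec("night ([0-9]+) condition (face|house|NA)", recInfo))[[1]]
  if (length(m) == 3L) {
    night <- as.integer(m[2])
    condition <- if (m[3] == "NA") NA_character_ else m[3]
  }
  new("EEGRecording", signal = sig, samplingRate = fs,
      channelNames = labels,
      subjectId = if (nzchar(patient)) patient else "unknown",
      night = night, condition = condition)
}

#' Write a results bundle as JSON (+ TSV time course)
#'
#' @param bundle list returned by \code{\link{runPipeline}}
#' @param dir output directory (created if needed)
#' @return the directory, invisibly
#' @export
writeResults <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  summ <- bundle$summary
  jsonlite::write_json(summ, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(bundle$timecourse))
    write.table(bundle$timecourse, file.path(dir, "timecourse.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(bundle$behaviourScores))
    write.csv(bundle$behaviourScores, file.path(dir, "behaviour_scores.csv"),
              row.names = FALSE)
  invisible(dir)
}

#' Export a cohort to disk
#'
#' Writes, under \code{dir}: one hypnogram TSV and (for signal-level
#' cohorts) one EDF file per night, the behaviour CSV, and a ground-truth
#' JSON (signature cells, stages, segments, realized per-night strengths,
#' and artefact information where present).
#'
#' @param cohort a \linkS4class{SleepCohort}
#' @param dir output directory (created if needed)
#' @return the directory, invisibly
#' @export
exportCohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nid in names(cohort@hypnograms))
    writeHypnogram(cohort@hypnograms[[nid]],
                   file.path(dir, paste0(nid, "_hypnogram.tsv")))
  if (cohort@level == "signal")
    for (nid in names(cohort@recordings))
      writeEdf(cohort@recordings[[nid]],
               file.path(dir, paste0(nid, ".edf")))
  writeBehaviour(cohort@behaviour, file.path(dir, "behaviour.csv"))
  truth <- list(
    signatureCells = cohort@truth$signatureCells,
    signatureStages = cohort@truth$signatureStages,
    signatureSegments = cohort@truth$signatureSegments,
    signatureAmplitude = cohort@config@signatureAmplitude,
    realizedStrength = as.list(cohort@truth$realizedStrength))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
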