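## --- EDF (European Data Format, 16-bit) writer / reader ------------------
## Minimal EDF support sufficient for round-tripping continuous recordings:
## one 1-s data record per second, physical units uV, per-signal scaling.

.padField <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)
}

#' Write a recording as a 16-bit EDF file
#'
#' @param rec an [EEGRecording-class]; duration is truncated to whole
#'   seconds (EDF stores fixed-length data records).
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
writeEDF <- function(rec, path) {
  stopifnot(is(rec, "EEGRecording"))
  ns <- nrow(rec@data)
  fs <- rec@fs
  nRec <- floor(ncol(rec@data) / fs)
  if (nRec < 1) stop("recording shorter than one EDF data record (1 s)")
  dat <- rec@data[, seq_len(nRec * fs), drop = FALSE]
  pmin_ <- apply(dat, 1, min); pmax_ <- apply(dat, 1, max)
  flat <- pmax_ - pmin_ < 1e-6
  pmax_[flat] <- pmin_[flat] + 1
  dmin <- -32768; dmax <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) writeChar(.padField(x, width), con, width,
                                     eos = NULL)
  wr("0", 8); wr(rec@subjectID, 80); wr("scdEEG synthetic", 80)
  wr("01.01.00", 8); wr("00.00.00", 8)
  wr(256 * (1 + ns), 8); wr("", 44); wr(nRec, 8); wr("1", 8); wr(ns, 4)
  for (x in rec@channels) wr(x, 16)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr("uV", 8)
  for (i in seq_len(ns)) wr(format(pmin_[i], digits = 6), 8)
  for (i in seq_len(ns)) wr(format(pmax_[i], digits = 6), 8)
  for (i in seq_len(ns)) wr(dmin, 8)
  for (i in seq_len(ns)) wr(dmax, 8)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr(fs, 8)
  for (i in seq_len(ns)) wr("", 32)
  gain <- (dmax - dmin) / (pmax_ - pmin_)
  for (r in seq_len(nRec)) {
    block <- dat[, ((r - 1) * fs + 1):(r * fs), drop = FALSE]
    dig <- round((block - pmin_) * gain + dmin)
    writeBin(as.integer(t(dig)), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read a 16-bit EDF file into an EEGRecording
#'
#' Channel labels are normalised to the study nomenclature
#' ([normalizeChannelLabels()]).
#'
#' @param path EDF file path.
#' @return An [EEGRecording-class].
#' @export
readEDF <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8)
  subj <- rd(80); rd(80); rd(8); rd(8); rd(8); rd(44)
  nRec <- as.integer(rd(8)); recDur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)
  pmin_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  pmax_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dmin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dmax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  for (i in seq_len(ns)) rd(80)
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), 0L)
  for (i in seq_len(ns)) rd(32)
  fs <- spr[1] / recDur
  dat <- matrix(0, ns, nRec * spr[1])
  for (r in seq_len(nRec)) {
    raw <- readBin(con, integer(), n = sum(spr), size = 2, endian = "little")
    off <- 0
    for (i in seq_len(ns)) {
      seg <- raw[(off + 1):(off + spr[i])]
      off <- off + spr[i]
      phys <- (seg - dmin[i]) / (dmax[i] - dmin[i]) * (pmax_[i] - pmin_[i]) +
        pmin_[i]
      dat[i, ((r - 1) * spr[i] + 1):(r * spr[i])] <- phys
    }
  }
  new("EEGRecording", subjectID = subj, data = dat, fs = fs,
      channels = normalizeChannelLabels(labels), metadata = list())
}

## --- delimited text recording (samples-per-second header) -----------------

#' Write a recording as a delimited text matrix
#'
#' Format: a first line `fs<TAB><rate>`, a channel-label header line, then
#' one row per sample (tab-separated microvolt values).
#'
#' @inheritParams writeEDF
#' @export
writeRecordingTable <- function(rec, path) {
  stopifnot(is(rec, "EEGRecording"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("fs\t", rec@fs), con)
  writeLines(paste(rec@channels, collapse = "\t"), con)
  write.table(format(t(rec@data), digits = 8, trim = TRUE), con, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a delimited text recording
#'
#' @param path file written by [writeRecordingTable()] (or any delimited
#'   numeric matrix with the same two header lines).
#' @param subjectID subject identifier to attach.
#' @return An [EEGRecording-class].
#' @export
readRecordingTable <- function(path, subjectID = basename(path)) {
  hdr <- readLines(path, n = 2)
  fs <- as.numeric(strsplit(hdr[1], "\t")[[1]][2])
  labels <- normalizeChannelLabels(strsplit(hdr[2], "\t")[[1]])
  dat <- as.matrix(read.table(path, sep = "\t", skip = 2))
  new("EEGRecording", subjectID = subjectID, data = t(unname(dat)), fs = fs,
      channels = labels, metadata = list())
}

#' Write a cohort to disk (EDF recordings + metadata table)
#'
#' Writes one EDF per subject plus a tab-delimited `metadata.tsv` with
#' subject id, group, age, sex, education, APOE4 and cognitive scores.
#'
#' @param cohort list as returned by `generateCohort(spec)` (with
#'   recordings).
#' @param dir output directory (created if needed).
#' @param format `"edf"` or `"table"`.
#' @return Invisibly, `dir`.
#' @export
writeCohort <- function(cohort, dir, format = c("edf", "table")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (rec in cohort$recordings) {
    f <- file.path(dir, paste0(rec@subjectID,
                               if (format == "edf") ".edf" else ".tsv"))
    if (format == "edf") writeEDF(rec, f) else writeRecordingTable(rec, f)
  }
  meta <- cohort$meta
  meta$severity <- NULL                 # latent variable, not observable
  write.table(meta, file.path(dir, "metadata.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Write a connectivity matrix with labelled header row and column
#'
#' @param cm a [ConnectivityMatrix-class].
#' @param path output path.
#' @export
writeConnectivityMatrix <- function(cm, path) {
  stopifnot(is(cm, "ConnectivityMatrix"))
  write.table(cbind(channel = rownames(cm@W), format(cm@W, digits = 8)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
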