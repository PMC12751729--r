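#' Zero-phase band-pass filter a continuous recording
#'
#' Applies a zero-phase band-pass in the frequency domain: unit gain over
#' `[lo, hi]`, raised-cosine transition bands of `transition` Hz on either
#' side, and zero gain beyond them. Exactly zero phase matters here because
#' phase distortion would bias the downstream weighted phase-lag index; the
#' sharp response fully suppresses mains frequencies a few Hz above the
#' 55 Hz edge. Filtering costs one FFT round-trip per channel.
#'
#' @param rec an [EEGRecording-class].
#' @param lo,hi band edges in Hz (defaults 1 and 55).
#' @param transition transition-band width in Hz (default 0.5, capped at
#'   `lo/2` so the stopband never crosses 0 Hz).
#' @return A filtered [EEGRecording-class] with identical shape and labels.
#' @export
bandpassFilter <- function(rec, lo = 1, hi = 55, transition = 0.5) {
  stopifnot(is(rec, "EEGRecording"))
  nyq <- rec@fs / 2
  if (!(lo > 0 && lo < hi)) stop("need 0 < lo < hi")
  if (hi >= nyq) stop("hi must be below the Nyquist frequency ", nyq, " Hz")
  n <- ncol(rec@data)
  w <- min(transition, lo / 2)
  k <- 0:(n - 1)
  f <- pmin(k, n - k) * rec@fs / n        # two-sided bin frequencies
  gain <- numeric(n)
  gain[f >= lo & f <= hi] <- 1
  rampLo <- f > lo - w & f < lo
  gain[rampLo] <- 0.5 * (1 + cos(pi * (lo - f[rampLo]) / w))
  rampHi <- f > hi & f < hi + w
  gain[rampHi] <- 0.5 * (1 + cos(pi * (f[rampHi] - hi) / w))
  out <- rec
  for (i in seq_len(nrow(rec@data)))
    out@data[i, ] <- Re(fft(fft(rec@data[i, ]) * gain, inverse = TRUE)) / n
  out
}

#' Segment a recording into consecutive fixed-length epochs
#'
#' Cuts the continuous signal into non-overlapping epochs of
#' `epochLength` seconds; a trailing partial segment is discarded.
#'
#' @param rec an [EEGRecording-class].
#' @param epochLength epoch length in seconds (default 2).
#' @return An [EpochSet-class] containing every full epoch, with
#'   `selectedIndices` covering all of them.
#' @export
segmentEpochs <- function(rec, epochLength = 2) {
  stopifnot(is(rec, "EEGRecording"))
  spe <- round(epochLength * rec@fs)
  nEp <- ncol(rec@data) %/% spe
  if (nEp < 1) stop("recording shorter than one epoch")
  arr <- array(NA_real_, c(nEp, nrow(rec@data), spe))
  for (e in seq_len(nEp))
    arr[e, , ] <- rec@data[, ((e - 1L) * spe + 1L):(e * spe)]
  new("EpochSet", subjectID = rec@subjectID, epochs = arr, fs = rec@fs,
      epochLength = epochLength, channels = rec@channels,
      selectedIndices = seq_len(nEp))
}

#' Flag artifact epochs and randomly select an analysis set
#'
#' Flags every epoch whose peak-to-peak amplitude on any channel exceeds
#' `ampThreshUV` (a deterministic, conservative stand-in for heavier
#' multi-stage cleaning chains; external cleaning can be applied to the
#' continuous data before this step), then uniformly samples `nSelect`
#' unflagged epochs without replacement.
#'
#' @param es an [EpochSet-class].
#' @param ampThreshUV peak-to-peak rejection threshold in microvolts
#'   (default 150).
#' @param nSelect number of epochs to retain (default 60).
#' @param seed integer seed fixing the random selection.
#' @return An [EpochSet-class] of exactly `nSelect` clean epochs whose
#'   `selectedIndices` (strictly increasing) refer to the input epoch
#'   numbering.
#' @export
rejectAndSelectEpochs <- function(es, ampThreshUV = 150, nSelect = 60, seed) {
  stopifnot(is(es, "EpochSet"))
  nEp <- dim(es@epochs)[1]
  if (nEp < 1) stop("empty epoch set")
  d <- dim(es@epochs)
  flat <- matrix(es@epochs, d[1] * d[2], d[3])   # (epoch, channel) x sample
  hi2 <- flat[, 1]; lo2 <- flat[, 1]
  for (j in 2:d[3]) {
    hi2 <- pmax(hi2, flat[, j]); lo2 <- pmin(lo2, flat[, j])
  }
  p2p <- apply(matrix(hi2 - lo2, d[1], d[2]), 1, max)
  clean <- which(p2p <= ampThreshUV)
  if (length(clean) < nSelect)
    stop(sprintf(
      "subject %s: only %d artifact-free epochs available, %d required",
      es@subjectID, length(clean), nSelect))
  keep <- withSeed(seed, sort(sample(clean, nSelect)))
  new("EpochSet", subjectID = es@subjectID,
      epochs = es@epochs[keep, , , drop = FALSE], fs = es@fs,
      epochLength = es@epochLength, channels = es@channels,
      selectedIndices = as.integer(es@selectedIndices[keep]))
}

#' Standard preprocessing chain for one subject
#'
#' Band-pass filters the continuous recording, segments it into 2-s epochs,
#' rejects amplitude artifacts and selects the analysis epoch set.
#'
#' @inheritParams bandpassFilter
#' @inheritParams rejectAndSelectEpochs
#' @param epochLength epoch length in seconds.
#' @return An [EpochSet-class] of selected clean epochs.
#' @export
preprocessRecording <- function(rec, lo = 1, hi = 55, epochLength = 2,
                                ampThreshUV = 150, nSelect = 60, seed = 1L) {
  rejectAndSelectEpochs(segmentEpochs(bandpassFilter(rec, lo, hi),
                                      epochLength),
                        ampThreshUV, nSelect, seed)
}
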