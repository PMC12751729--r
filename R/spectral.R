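#' The five classical EEG frequency bands
#'
#' Band edges are half-open `[lo, hi)` except gamma, whose upper edge 55 Hz
#' is inclusive, so the five bands exactly partition the 1-55 Hz analysis
#' range without double-counting boundary bins.
#'
#' @return data.frame with columns `name`, `lo`, `hi`.
#' @export
#' @examples
#' bandDefinitions()
bandDefinitions <- function() {
  data.frame(name = c("delta", "theta", "alpha", "beta", "gamma"),
             lo = c(1, 4, 8, 12, 30),
             hi = c(4, 8, 12, 30, 55),
             stringsAsFactors = FALSE)
}

## Hamming window of length n (periodic coefficients as used for spectral
## averaging).
.hamming <- function(n) 0.54 - 0.46 * cos(2 * pi * seq(0, n - 1) / (n - 1))

## Windowed FFT of every epoch: returns list(coefs = epochs x channels x bins
## complex array over one-sided bins, freq, U = window power, nfft).
.epochFFT <- function(es) {
  d <- dim(es@epochs)
  nS <- d[3]
  w <- .hamming(nS)
  U <- mean(w^2)
  nBins <- floor(nS / 2) + 1L
  freq <- (seq_len(nBins) - 1L) * es@fs / nS
  coefs <- array(complex(1), c(d[1], d[2], nBins))
  for (e in seq_len(d[1])) {
    seg <- t(es@epochs[e, , , drop = TRUE])          # samples x channels
    if (d[2] == 1L) seg <- matrix(es@epochs[e, 1, ], ncol = 1)
    ft <- mvfft(seg * w)
    coefs[e, , ] <- t(ft[seq_len(nBins), , drop = FALSE])
  }
  list(coefs = coefs, freq = freq, U = U, nfft = nS)
}

#' Welch power spectral density over epochs
#'
#' Each epoch is one Hamming-windowed Welch segment (no sub-segmentation or
#' overlap: non-overlapping 2-s epochs are the natural independent averaging
#' unit and give 0.5 Hz resolution, which resolves every band edge).
#' Modified periodograms are averaged across epochs with the standard
#' window-power normalisation, so `sum(psd * df)` approximates the signal
#' variance.
#'
#' @param es an [EpochSet-class] with at least one epoch.
#' @param ft optional precomputed epoch FFT (internal reuse).
#' @return A list with `freq` (Hz) and `psd` (channels x bins matrix,
#'   microvolts squared per Hz, one-sided).
#' @export
welchPsd <- function(es, ft = NULL) {
  stopifnot(is(es, "EpochSet"))
  if (dim(es@epochs)[1] < 1) stop("at least one epoch required")
  if (is.null(ft)) ft <- .epochFFT(es)
  nS <- ft$nfft
  nBins <- length(ft$freq)
  ## mean over epochs of |X|^2, scaled to a one-sided density
  p <- colMeans(Mod(ft$coefs)^2, dims = 1) / (es@fs * nS * ft$U)
  scale <- rep(2, nBins)
  scale[1] <- 1
  if (nS %% 2 == 0) scale[nBins] <- 1
  psd <- sweep(p, 2, scale, `*`)
  rownames(psd) <- es@channels
  list(freq = ft$freq, psd = psd)
}

#' Relative band power features
#'
#' Per channel, band power is the sum of PSD bins with `lo <= f < hi` (55 Hz
#' inclusive in gamma) and relative power is 100 x band power / total power
#' over 1-55 Hz. A `Global` location (arithmetic mean over the 19 channels)
#' is appended, so per location the five bands sum to 100.
#'
#' @param psd result of [welchPsd()].
#' @param bands band definition data.frame (default [bandDefinitions()]).
#' @return matrix bands x locations (channels + `"Global"`), in percent.
#' @export
relativeBandPower <- function(psd, bands = bandDefinitions()) {
  f <- psd$freq
  total <- f >= min(bands$lo) & f <= max(bands$hi)
  bp <- matrix(NA_real_, nrow(bands), nrow(psd$psd),
               dimnames = list(bands$name, rownames(psd$psd)))
  for (i in seq_len(nrow(bands))) {
    inBand <- if (bands$hi[i] == max(bands$hi))
      f >= bands$lo[i] & f <= bands$hi[i]
    else f >= bands$lo[i] & f < bands$hi[i]
    if (!any(inBand))
      stop("band '", bands$name[i], "' contains no frequency bins")
    bp[i, ] <- rowSums(psd$psd[, inBand, drop = FALSE])
  }
  tot <- rowSums(psd$psd[, total, drop = FALSE])
  rel <- 100 * sweep(bp, 2, tot, `/`)
  cbind(rel, Global = rowMeans(rel))
}

#' Spectral features for one subject
#'
#' Convenience wrapper: Welch PSD then relative band power, returned as a
#' named feature vector `<band>_power_<channel|Global>`.
#'
#' @param es an [EpochSet-class].
#' @return Named numeric vector of 100 relative-power features (percent).
#' @export
spectralFeatures <- function(es) {
  rel <- relativeBandPower(welchPsd(es))
  out <- as.vector(t(rel))
  names(out) <- paste0(rep(rownames(rel), each = ncol(rel)), "_power_",
                       rep(colnames(rel), nrow(rel)))
  out
}
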