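#' Weighted phase-lag index matrix for one band
#'
#' Per epoch, a Hamming-tapered FFT gives the cross-spectrum
#' `S_xy(f) = X(f) * Conj(Y(f))` for every channel pair. Per frequency bin,
#' `wPLI(f) = |mean_epochs Im S_xy(f)| / mean_epochs |Im S_xy(f)|`, with 0/0
#' defined as 0; the band value is the unweighted mean of `wPLI(f)` over the
#' bins inside the band. Because only the imaginary part of the
#' cross-spectrum enters, instantaneous (zero-lag) mixing such as volume
#' conduction contributes nothing.
#'
#' @param es an [EpochSet-class] with at least two epochs (the estimator is
#'   undefined for a single epoch).
#' @param band one row of [bandDefinitions()] (or any list with `name`,
#'   `lo`, `hi`).
#' @return A [ConnectivityMatrix-class].
#' @export
wpliMatrix <- function(es, band) {
  stopifnot(is(es, "EpochSet"))
  if (dim(es@epochs)[1] < 2)
    stop("wPLI requires at least two epochs")
  cs <- .crossSpectra(es)
  .wpliFromCross(cs, band, es@subjectID)
}

## Accumulated imaginary cross-spectrum sums for all pairs and one-sided
## bins: list(freq, sumIm, sumAbsIm, pairs(i, j), nCh, nEpochs).
.crossSpectra <- function(es, ft = NULL) {
  if (is.null(ft)) ft <- .epochFFT(es)
  d <- dim(ft$coefs)                    # epochs x channels x bins
  nCh <- d[2]
  pairIdx <- which(upper.tri(matrix(0, nCh, nCh)), arr.ind = TRUE)
  pairIdx <- pairIdx[order(pairIdx[, 1], pairIdx[, 2]), , drop = FALSE]
  iIdx <- pairIdx[, 1]; jIdx <- pairIdx[, 2]
  sumIm <- matrix(0, nrow(pairIdx), d[3])
  sumAbsIm <- matrix(0, nrow(pairIdx), d[3])
  for (e in seq_len(d[1])) {
    Fe <- ft$coefs[e, , , drop = TRUE]
    if (nCh == 1L) Fe <- matrix(Fe, nrow = 1)
    ReF <- Re(Fe); ImF <- Im(Fe)
    ## Im(X_i Conj(X_j)) = Im_i Re_j - Re_i Im_j
    imS <- ImF[iIdx, , drop = FALSE] * ReF[jIdx, , drop = FALSE] -
      ReF[iIdx, , drop = FALSE] * ImF[jIdx, , drop = FALSE]
    sumIm <- sumIm + imS
    sumAbsIm <- sumAbsIm + abs(imS)
  }
  list(freq = ft$freq, sumIm = sumIm, sumAbsIm = sumAbsIm,
       i = iIdx, j = jIdx, nCh = nCh, nEpochs = d[1],
       channels = es@channels)
}

## Band-average wPLI matrix from accumulated cross-spectra.
.wpliFromCross <- function(cs, band, subjectID = "s") {
  inclusiveHi <- band$hi >= 55
  inBand <- if (inclusiveHi) cs$freq >= band$lo & cs$freq <= band$hi
  else cs$freq >= band$lo & cs$freq < band$hi
  if (!any(inBand)) stop("band '", band$name, "' contains no frequency bins")
  num <- abs(cs$sumIm[, inBand, drop = FALSE])
  den <- cs$sumAbsIm[, inBand, drop = FALSE]
  w <- ifelse(den > 0, num / den, 0)
  pairVal <- rowMeans(w)
  W <- matrix(0, cs$nCh, cs$nCh, dimnames = list(cs$channels, cs$channels))
  W[cbind(cs$i, cs$j)] <- pairVal
  W <- W + t(W)
  new("ConnectivityMatrix", subjectID = subjectID,
      band = as.character(band$name), W = W)
}

#' wPLI matrices for all bands
#'
#' Computes the epoch-wise cross-spectra once and derives the band-averaged
#' wPLI matrix for every requested band.
#'
#' @param es an [EpochSet-class] (>= 2 epochs).
#' @param bands band definition data.frame (default [bandDefinitions()]).
#' @param ft optional precomputed epoch FFT (internal reuse).
#' @return Named list of [ConnectivityMatrix-class], one per band.
#' @export
wpliAllBands <- function(es, bands = bandDefinitions(), ft = NULL) {
  stopifnot(is(es, "EpochSet"))
  if (dim(es@epochs)[1] < 2) stop("wPLI requires at least two epochs")
  cs <- .crossSpectra(es, ft)
  out <- lapply(seq_len(nrow(bands)), function(i)
    .wpliFromCross(cs, bands[i, ], es@subjectID))
  names(out) <- bands$name
  out
}
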