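#' The 19-channel 10-20 montage used throughout the package
#'
#' Channel labels of the classical 19-electrode international 10-20 montage
#' with the legacy temporal names (T3/T4/T5/T6), in the fixed order used by
#' every matrix and feature name in this package.
#'
#' @return Character vector of 19 channel labels.
#' @export
#' @examples
#' montage1020()
montage1020 <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
    "T3", "C3", "Cz", "C4", "T4",
    "T5", "P3", "Pz", "P4", "T6",
    "O1", "O2")
}

## Modern-to-legacy synonym map applied when reading external recordings.
.channelSynonyms <- c(T7 = "T3", T8 = "T4", P7 = "T5", P8 = "T6")

#' Normalise channel labels to the study nomenclature
#'
#' Maps modern temporal labels (T7, T8, P7, P8) to the legacy 10-20 names
#' (T3, T4, T5, T6) and strips common reference suffixes such as "-A1".
#'
#' @param labels character vector of channel labels.
#' @return Character vector of normalised labels.
#' @export
normalizeChannelLabels <- function(labels) {
  x <- sub("-.*$", "", trimws(labels))
  hit <- x %in% names(.channelSynonyms)
  x[hit] <- .channelSynonyms[x[hit]]
  x
}

## Frontal / posterior channel index helpers used by the generator topography.
.frontalChannels <- c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8")
.posteriorChannels <- c("T5", "P3", "Pz", "P4", "T6", "O1", "O2")
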