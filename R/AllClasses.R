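#' EEGRecording: one subject's continuous multichannel EEG
#'
#' Container for a continuous multichannel recording in microvolts, with its
#' sampling rate and ordered channel labels. Cohort-level study invariants
#' (the full 19-channel 10-20 montage, at least 180 s of signal) are enforced
#' by the generator and by [checkStudyRecording()], not by class validity, so
#' that short single-purpose signals remain constructible for calibration.
#'
#' @slot subjectID single character identifier.
#' @slot data channels x samples numeric matrix (microvolts).
#' @slot fs sampling rate in Hz.
#' @slot channels ordered channel labels, one per row of `data`.
#' @slot metadata free-form list (e.g. injected artifact event log).
#' @export
setClass("EEGRecording",
  representation(subjectID = "character", data = "matrix", fs = "numeric",
                 channels = "character", metadata = "list"),
  prototype(subjectID = "s", fs = 250, metadata = list()))

setValidity("EEGRecording", function(object) {
  msg <- character()
  if (length(object@fs) != 1L || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  if (nrow(object@data) != length(object@channels))
    msg <- c(msg, "one channel label per data row required")
  if (anyDuplicated(object@channels))
    msg <- c(msg, "channel labels must be unique")
  if (length(object@data) && !all(is.finite(object@data)))
    msg <- c(msg, "all samples must be finite")
  if (length(msg)) msg else TRUE
})

#' EpochSet: fixed-length artifact-screened epochs for one subject
#'
#' @slot subjectID subject identifier.
#' @slot epochs epochs x channels x samples numeric array (microvolts).
#' @slot fs sampling rate (Hz).
#' @slot epochLength epoch length in seconds.
#' @slot channels ordered channel labels.
#' @slot selectedIndices indices of the retained epochs in the original
#'   segmentation (strictly increasing).
#' @export
setClass("EpochSet",
  representation(subjectID = "character", epochs = "array", fs = "numeric",
                 epochLength = "numeric", channels = "character",
                 selectedIndices = "integer"))

setValidity("EpochSet", function(object) {
  d <- dim(object@epochs)
  msg <- character()
  if (length(d) != 3L)
    msg <- c(msg, "epochs must be a 3-d array (epochs x channels x samples)")
  else {
    if (d[2] != length(object@channels))
      msg <- c(msg, "channel labels must match the second array dimension")
    if (d[3] != round(object@epochLength * object@fs))
      msg <- c(msg, "samples per epoch must equal epochLength * fs")
    if (length(object@selectedIndices) &&
        (length(object@selectedIndices) != d[1] ||
         is.unsorted(object@selectedIndices, strictly = TRUE)))
      msg <- c(msg, "selectedIndices must be strictly increasing, one per epoch")
  }
  if (length(msg)) msg else TRUE
})

#' ConnectivityMatrix: per-band symmetric wPLI matrix
#'
#' @slot subjectID subject identifier.
#' @slot band band name.
#' @slot W symmetric nonnegative matrix with zero diagonal, entries in [0,1],
#'   channel labels as dimnames.
#' @export
setClass("ConnectivityMatrix",
  representation(subjectID = "character", band = "character", W = "matrix"))

setValidity("ConnectivityMatrix", function(object) {
  W <- object@W
  msg <- character()
  if (nrow(W) != ncol(W)) msg <- c(msg, "W must be square")
  else {
    if (!isTRUE(all.equal(W, t(W), tolerance = 1e-10)))
      msg <- c(msg, "W must be symmetric")
    if (any(diag(W) != 0)) msg <- c(msg, "W must have a zero diagonal")
    if (any(W < 0 | W > 1)) msg <- c(msg, "entries must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' CVResult: stratified cross-validation outcome for one classifier run
#'
#' @slot folds data.frame of per-fold confusion counts and metrics.
#' @slot metrics data.frame with one row per metric: pooled value (from summed
#'   confusion counts), mean and sd across folds.
#' @slot selectedFeatures ordered character vector of features used.
#' @slot permP named numeric vector of permutation p-values (empty until
#'   [permutationPvalue()] is run).
#' @slot nFolds number of folds.
#' @slot seed integer seed that fixed folds, SMOTE and training.
#' @export
setClass("CVResult",
  representation(folds = "data.frame", metrics = "data.frame",
                 selectedFeatures = "character", permP = "numeric",
                 nFolds = "integer", seed = "integer"))

#' ShapSummary: exact Shapley attributions for a stump ensemble
#'
#' @slot values samples x features matrix of attributions; positive values
#'   push the prediction toward the positive (amyloid-positive) class.
#' @slot baseValue scalar expected model margin over the background set.
#' @slot meanAbs named per-feature mean absolute attribution.
#' @slot topK ranked names of the `k` features with largest meanAbs.
#' @export
setClass("ShapSummary",
  representation(values = "matrix", baseValue = "numeric",
                 meanAbs = "numeric", topK = "character"))
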