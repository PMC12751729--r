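#' Accessors for scdEEG S4 classes
#'
#' Slot accessors for [EEGRecording-class], [EpochSet-class],
#' [ConnectivityMatrix-class] and [CVResult-class] objects.
#'
#' @param x an scdEEG S4 object.
#' @name accessors
#' @aliases samplingRate channelLabels subjectID eegData epochArray nEpochs
#'   selectedIndices bandName connMatrix cvMetrics selectedFeatures
#'   permPvalues
NULL

#' @rdname accessors
setMethod("samplingRate", "EEGRecording", function(x) x@fs)
#' @rdname accessors
setMethod("samplingRate", "EpochSet", function(x) x@fs)
#' @rdname accessors
setMethod("channelLabels", "EEGRecording", function(x) x@channels)
#' @rdname accessors
setMethod("channelLabels", "EpochSet", function(x) x@channels)
#' @rdname accessors
setMethod("subjectID", "EEGRecording", function(x) x@subjectID)
#' @rdname accessors
setMethod("subjectID", "EpochSet", function(x) x@subjectID)
#' @rdname accessors
setMethod("subjectID", "ConnectivityMatrix", function(x) x@subjectID)
#' @rdname accessors
setMethod("eegData", "EEGRecording", function(x) x@data)
#' @rdname accessors
setMethod("epochArray", "EpochSet", function(x) x@epochs)
#' @rdname accessors
setMethod("nEpochs", "EpochSet", function(x) dim(x@epochs)[1])
#' @rdname accessors
setMethod("selectedIndices", "EpochSet", function(x) x@selectedIndices)
#' @rdname accessors
setMethod("bandName", "ConnectivityMatrix", function(x) x@band)
#' @rdname accessors
setMethod("connMatrix", "ConnectivityMatrix", function(x) x@W)
#' @rdname accessors
setMethod("cvMetrics", "CVResult", function(x) x@metrics)
#' @rdname accessors
setMethod("selectedFeatures", "CVResult", function(x) x@selectedFeatures)
#' @rdname accessors
setMethod("permPvalues", "CVResult", function(x) x@permP)

setMethod("show", "EEGRecording", function(object) {
  cat(sprintf("EEGRecording '%s': %d channels x %d samples @ %g Hz (%.1f s)\n",
              object@subjectID, nrow(object@data), ncol(object@data),
              object@fs, ncol(object@data) / object@fs))
})

setMethod("show", "EpochSet", function(object) {
  d <- dim(object@epochs)
  cat(sprintf("EpochSet '%s': %d epochs of %g s (%d channels @ %g Hz)\n",
              object@subjectID, d[1], object@epochLength, d[2], object@fs))
})

setMethod("show", "ConnectivityMatrix", function(object) {
  cat(sprintf("ConnectivityMatrix '%s' [%s]: %d x %d, mean off-diag %.3f\n",
              object@subjectID, object@band, nrow(object@W), ncol(object@W),
              mean(object@W[upper.tri(object@W)])))
})

setMethod("show", "CVResult", function(object) {
  cat(sprintf("CVResult: %d-fold stratified CV, %d features, seed %d\n",
              object@nFolds, length(object@selectedFeatures), object@seed))
  m <- object@metrics
  for (i in seq_len(nrow(m)))
    cat(sprintf("  %-11s %.3f (fold mean %.3f +/- %.3f)%s\n", m$metric[i],
                m$pooled[i], m$mean[i], m$sd[i],
                if (length(object@permP) &&
                    m$metric[i] %in% names(object@permP))
                  sprintf("  P_perm = %.4g", object@permP[[m$metric[i]]])
                else ""))
})

setMethod("show", "ShapSummary", function(object) {
  cat(sprintf("ShapSummary: %d samples x %d features, base value %.4f\n",
              nrow(object@values), ncol(object@values), object@baseValue))
  cat("  top features by mean |SHAP|:\n")
  for (f in object@topK)
    cat(sprintf("    %-24s %.4f\n", f, object@meanAbs[[f]]))
})
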