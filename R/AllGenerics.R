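#' @rdname RawRecording-class
#' @param object,x a package object.
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname RawRecording-class
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @rdname RawRecording-class
#' @export
setGeneric("channelRoles", function(x) standardGeneric("channelRoles"))

#' @rdname RawRecording-class
#' @export
setGeneric("recordingData", function(x) standardGeneric("recordingData"))

#' @rdname RawRecording-class
#' @export
setGeneric("annotations", function(x) standardGeneric("annotations"))

#' @rdname EpochedRecording-class
#' @export
setGeneric("nEpochs", function(x) standardGeneric("nEpochs"))

#' @rdname EpochedRecording-class
#' @export
setGeneric("epochArray", function(x) standardGeneric("epochArray"))

#' @rdname EpochedRecording-class
#' @export
setGeneric("epochStates", function(x) standardGeneric("epochStates"))

#' @rdname EpochedRecording-class
#' @export
setGeneric("epochSubjects", function(x) standardGeneric("epochSubjects"))

#' @rdname RawRecording-class
setMethod("samplingRate", "RawRecording", function(x) x@fs)
#' @rdname EpochedRecording-class
setMethod("samplingRate", "EpochedRecording", function(x) x@fs)
#' @rdname RawRecording-class
setMethod("channelNames", "RawRecording", function(x) x@channels)
#' @rdname EpochedRecording-class
setMethod("channelNames", "EpochedRecording", function(x) x@channels)
#' @rdname RawRecording-class
setMethod("channelRoles", "RawRecording", function(x)
  setNames(x@roles, x@channels))
#' @rdname RawRecording-class
setMethod("recordingData", "RawRecording", function(x) x@data)
#' @rdname RawRecording-class
setMethod("annotations", "RawRecording", function(x) x@annotations)
#' @rdname EpochedRecording-class
setMethod("nEpochs", "EpochedRecording", function(x) dim(x@epochs)[1])
#' @rdname EpochedRecording-class
setMethod("epochArray", "EpochedRecording", function(x) x@epochs)
#' @rdname EpochedRecording-class
setMethod("epochStates", "EpochedRecording", function(x) x@state)
#' @rdname EpochedRecording-class
setMethod("epochSubjects", "EpochedRecording", function(x) x@subject)

setMethod("show", "RawRecording", function(object) {
  cat(sprintf("RawRecording: %d channels x %d samples @ %g Hz (%.1f s)\n",
              ncol(object@data), nrow(object@data), object@fs,
              nrow(object@data) / object@fs))
  cat("  channels:",
      paste(sprintf("%s[%s]", object@channels, object@roles), collapse = " "),
      "\n")
  if (nrow(object@annotations))
    cat(sprintf("  %d annotated segment(s), states: %s\n",
                nrow(object@annotations),
                paste(unique(object@annotations$state), collapse = ", ")))
})

setMethod("show", "EpochedRecording", function(object) {
  d <- dim(object@epochs)
  cat(sprintf("EpochedRecording: %d epochs x %d channels x %d samples @ %g Hz\n",
              d[1], d[2], d[3], object@fs))
  print(table(state = object@state))
})

setMethod("show", "StateSpec", function(object) {
  cat(sprintf("StateSpec '%s': %d subjects x %d epochs, total power %g uV^2\n",
              object@state, object@nSubjects, object@epochsPerSubject,
              object@totalPower))
  m <- rbind(mean = object@bandRelMean, sd = object@bandRelSD)
  print(round(m, 3))
})

setMethod("show", "BandScheme", function(object) {
  cat("BandScheme over", paste(object@totalRange, collapse = "-"), "Hz\n")
  print(object@bands)
})

setMethod("show", "PSDEstimate", function(object) {
  cat(sprintf("PSDEstimate: %d channels, %d bins, %g-%g Hz (df = %g Hz)\n",
              length(object@channels), length(object@freqs),
              min(object@freqs), max(object@freqs),
              object@freqs[2] - object@freqs[1]))
})

setMethod("show", "ClassifierFit", function(object) {
  cat(sprintf("ClassifierFit '%s' on %d features, classes: %s\n",
              object@kind, length(object@featureNames),
              paste(object@classLevels, collapse = ", ")))
  cat(sprintf("  cross-validated accuracy: %.3f (%d folds)\n",
              object@cvAccuracy, length(object@foldAccuracy)))
})

setMethod("show", "ClassifierReport", function(object) {
  cat(sprintf("ClassifierReport '%s' (%s): overall accuracy %.2f%%\n",
              object@kind, object@task, 100 * object@overallAccuracy))
  print(object@confusion)
  if (!is.na(object@auc))
    cat(sprintf("  AUC %.3f, Gini %.3f\n", object@auc, object@gini))
})

#' Bands of a scheme
#'
#' @param scheme a [BandScheme-class].
#' @return the named (low, high) band matrix in Hz.
#' @export
bandMatrix <- function(scheme) scheme@bands

#' @rdname bandMatrix
#' @return `bandNames`: the band names in scheme order.
#' @export
bandNames <- function(scheme) rownames(scheme@bands)
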