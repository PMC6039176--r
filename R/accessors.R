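## Accessor generics for the main containers. Slot access stays internal.

#' Extract the data values of a container
#' @param x a fusmap data object.
#' @return The underlying numeric/complex array or matrix.
#' @export
setGeneric("values", function(x) standardGeneric("values"))

#' @rdname values
#' @export
setMethod("values", "FrameBlock", function(x) x@data)
#' @rdname values
#' @export
setMethod("values", "PowerDopplerSeries", function(x) x@values)
#' @rdname values
#' @export
setMethod("values", "CBVSeries", function(x) x@values)
#' @rdname values
#' @export
setMethod("values", "TrialTensor", function(x) x@values)
#' @rdname values
#' @export
setMethod("values", "ResponseSet", function(x) x@values)

#' Stimulus labels of a trial container
#' @param x a [TrialTensor-class], [ResponseSet-class] or
#'   [DecodingDataset-class].
#' @return Character vector, one label per trial.
#' @export
setGeneric("labels")
#' @rdname labels
#' @export
setMethod("labels", "TrialTensor", function(object, ...) object@labels)
#' @rdname labels
#' @export
setMethod("labels", "ResponseSet", function(object, ...) object@labels)
#' @rdname labels
#' @export
setMethod("labels", "DecodingDataset", function(object, ...) object@y)

#' Acquisition configuration of a frame block
#' @param x a [FrameBlock-class].
#' @return The [AcquisitionConfig-class].
#' @export
acqConfig <- function(x) x@config

#' Best-frequency indices
#' @param x a [TuningMap-class] or [BFMap-class].
#' @return Integer (TuningMap) or numeric array (BFMap) of best frequencies.
#' @export
setGeneric("bfIndex", function(x) standardGeneric("bfIndex"))
#' @rdname bfIndex
#' @export
setMethod("bfIndex", "TuningMap", function(x) x@bfIndex)
#' @rdname bfIndex
#' @export
setMethod("bfIndex", "BFMap", function(x) x@bf)

#' Tuning curve of a tuning map
#' @param x a [TuningMap-class].
#' @return nfreq x nvoxel matrix of mean responses.
#' @export
tuningCurve <- function(x) x@curve

#' ANOVA p-values of a tuning map
#' @param x a [TuningMap-class].
#' @return Numeric vector per voxel.
#' @export
anovaP <- function(x) x@anovaP

#' Display mask of a best-frequency map
#' @param x a [BFMap-class].
#' @return Logical array.
#' @export
displayMaskOf <- function(x) x@mask

#' Decoding accuracy
#' @param x a [DecodingResult-class].
#' @return Overall accuracy.
#' @export
accuracy <- function(x) x@accuracy

#' Null distribution of a permutation test
#' @param x a [DecodingResult-class].
#' @return Numeric vector of null accuracies.
#' @export
nullDistribution <- function(x) x@null

#' Permutation p-value
#' @param x a [DecodingResult-class].
#' @return p-value (NA when no permutation test was run).
#' @export
pValue <- function(x) x@pValue

#' Functional resolution estimates
#' @param x a [ResolutionCurve-class].
#' @return Named numeric, micrometres, `c(responsiveness=, tuning=)`.
#' @export
resolutionOf <- function(x) x@resolution
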