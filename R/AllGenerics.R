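#' @include utils.R
NULL

#' Number of trials, channels and samples
#'
#' Dimension accessors for epoch containers.
#'
#' @param x an object with an epoch dimension (e.g. [EpochArray-class]).
#' @return an integer scalar.
#' @export
#' @rdname epoch-dims
setGeneric("nTrials", function(x) standardGeneric("nTrials"))

#' @export
#' @rdname epoch-dims
setGeneric("nChannels", function(x) standardGeneric("nChannels"))

#' @export
#' @rdname epoch-dims
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' Sampling rate in Hz
#' @param x an epoch container.
#' @return numeric scalar, Hz.
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' Time axis in milliseconds relative to the first-cue onset
#' @param x an epoch container.
#' @return numeric vector of sample times (ms).
#' @export
setGeneric("timesMs", function(x) standardGeneric("timesMs"))

#' Trial metadata table
#'
#' The per-trial table (condition labels, cue glyphs, event times, correctness
#' flags) aligned 1:1 with the trial axis of the data.
#'
#' @param x a design or epoch container.
#' @return a `data.frame` with one row per trial.
#' @export
setGeneric("trialTable", function(x) standardGeneric("trialTable"))

#' Channel metadata
#' @param x an epoch container or leadfield.
#' @return a `data.frame` with one row per channel (name, 3-D position).
#' @export
setGeneric("channelInfo", function(x) standardGeneric("channelInfo"))

#' Raw epoch data array
#' @param x an epoch container.
#' @return numeric array `trials x channels x samples`.
#' @export
setGeneric("epochData", function(x) standardGeneric("epochData"))

#' Hemisphere labels of a source space
#' @param x a [SourceSpace-class].
#' @return character vector, `"left"`/`"right"` per source.
#' @export
setGeneric("hemispheres", function(x) standardGeneric("hemispheres"))

#' Information values of a decoding result
#' @param x an [InformationResult-class] or [SearchlightResult-class].
#' @return numeric vector/matrix of pattern distinctness values.
#' @export
setGeneric("informationValues", function(x) standardGeneric("informationValues"))
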