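#' @include AllClasses.R
NULL

#' Construct an EpochArray
#'
#' @param data numeric array `trials x channels x samples`.
#' @param samplingRate sampling rate, Hz.
#' @param tstartMs time of the first sample (ms, relative to cue-1 onset).
#' @param channels channel metadata `data.frame` (`name`, `x`, `y`, `z`);
#'   generated if missing.
#' @param trials trial table aligned with the first axis; empty if missing.
#' @return an [EpochArray-class].
#' @export
epochArray <- function(data, samplingRate, tstartMs = 0,
                       channels = NULL, trials = NULL) {
  data <- as.array(data)
  stopIfNot(length(dim(data)) == 3L, "data must be trials x channels x samples")
  if (is.null(channels))
    channels <- data.frame(name = sprintf("CH%03d", seq_len(dim(data)[2L])),
                           x = 0, y = 0, z = 0)
  if (is.null(trials))
    trials <- data.frame(trial = seq_len(dim(data)[1L]))
  new("EpochArray", data = data, samplingRate = as.numeric(samplingRate),
      tstartMs = as.numeric(tstartMs), channels = channels, trials = trials)
}

#' @rdname epoch-dims
#' @export
setMethod("nTrials", "EpochArray", function(x) dim(x@data)[1L])
#' @rdname epoch-dims
#' @export
setMethod("nChannels", "EpochArray", function(x) dim(x@data)[2L])
#' @rdname epoch-dims
#' @export
setMethod("nSamples", "EpochArray", function(x) dim(x@data)[3L])

#' @export
#' @describeIn samplingRate sampling rate of an epoch array.
setMethod("samplingRate", "EpochArray", function(x) x@samplingRate)

#' @export
#' @describeIn timesMs sample times of an epoch array.
setMethod("timesMs", "EpochArray", function(x)
  x@tstartMs + (seq_len(nSamples(x)) - 1L) * 1000 / x@samplingRate)

#' @export
#' @describeIn trialTable trial table of an epoch array.
setMethod("trialTable", "EpochArray", function(x) x@trials)

#' @export
#' @describeIn channelInfo channel metadata of an epoch array.
setMethod("channelInfo", "EpochArray", function(x) x@channels)

#' @export
#' @describeIn epochData data array of an epoch array.
setMethod("epochData", "EpochArray", function(x) x@data)

setMethod("show", "EpochArray", function(object) {
  cat(sprintf(
    "EpochArray: %d trials x %d channels x %d samples @ %.6g Hz\n",
    nTrials(object), nChannels(object), nSamples(object),
    object@samplingRate))
  tm <- timesMs(object)
  cat(sprintf("  time %.1f .. %.1f ms (cue-1 onset = 0)\n",
              tm[1L], tm[length(tm)]))
  if (ncol(object@trials))
    cat("  trial table:", paste(names(object@trials), collapse = ", "), "\n")
})

#' Subset an EpochArray
#'
#' Selection along any of the three axes; trial and channel metadata are
#' subset consistently and the time origin is updated.
#'
#' @param x an [EpochArray-class].
#' @param trials,channels,samples index vectors (missing = keep all).
#' @return an [EpochArray-class].
#' @export
subsetEpochs <- function(x, trials = NULL, channels = NULL, samples = NULL) {
  trials <- trials %||% seq_len(nTrials(x))
  channels <- channels %||% seq_len(nChannels(x))
  samples <- samples %||% seq_len(nSamples(x))
  tm <- timesMs(x)[samples]
  fs <- x@samplingRate
  if (length(tm) > 1L) {
    dt <- diff(tm)
    stopIfNot(max(abs(dt - dt[1L])) < 1e-9,
              "sample subsets must be evenly spaced")
    fs <- 1000 / dt[1L]
  }
  new("EpochArray",
      data = x@data[trials, channels, samples, drop = FALSE],
      samplingRate = fs, tstartMs = tm[1L],
      channels = x@channels[channels, , drop = FALSE],
      trials = x@trials[trials, , drop = FALSE])
}

## ---- other show/accessor methods -------------------------------------

#' @export
#' @describeIn trialTable trial table of a session design.
setMethod("trialTable", "SessionDesign", function(x) x@trials)

#' @export
#' @describeIn trialTable trial table of a simulated dataset.
setMethod("trialTable", "SimulatedDataset", function(x) x@design@trials)

setMethod("show", "SessionDesign", function(object) {
  cat(sprintf(
    "SessionDesign: participant %s, session %d, %d trials\n",
    object@participant, object@session, nrow(object@trials)))
  cat("  block order (rules):", paste(object@blockOrder, collapse = " "), "\n")
})

#' @export
#' @describeIn hemispheres hemisphere labels of a source space.
setMethod("hemispheres", "SourceSpace", function(x) x@hemisphere)

setMethod("show", "SourceSpace", function(object) {
  cat(sprintf(
    "SourceSpace: %d sources on a %.3g m shell (%d left / %d right)\n",
    nrow(object@positions), object@radius,
    sum(object@hemisphere == "left"), sum(object@hemisphere == "right")))
  cat(sprintf("  neighbor degree: median %d\n",
              stats::median(lengths(object@neighbors))))
})

setMethod("show", "Leadfield", function(object) {
  d <- dim(object@gain)
  cat(sprintf("Leadfield: %d sources x 3 orientations x %d channels\n",
              d[1L], d[3L]))
})

setMethod("show", "SimulatedDataset", function(object) {
  cat("SimulatedDataset\n")
  show(object@design)
  show(object@epochs)
  cat(sprintf("  audio: %s\n",
              if (is.null(object@audio)) "none"
              else sprintf("%d trials @ %.6g Hz", nrow(object@audio),
                           object@audioRate)))
})

setMethod("show", "Contrast", function(object) {
  inc <- rowSums(object@weights != 0) > 0
  cat(sprintf("Contrast '%s': %d columns over %d of %d conditions\n",
              object@variable, ncol(object@weights), sum(inc),
              nrow(object@weights)))
})

setMethod("show", "InformationResult", function(object) {
  cat(sprintf("InformationResult [%s] variable '%s'\n",
              object@mode, object@variable))
  if (is.matrix(object@values))
    cat(sprintf("  %d train x %d test time points\n",
                nrow(object@values), ncol(object@values)))
  else
    cat(sprintf("  %d time points, mean D = %.4g\n",
                length(object@values), mean(object@values)))
})

#' @export
#' @describeIn informationValues values of a decoding result.
setMethod("informationValues", "InformationResult", function(x) x@values)

#' @export
#' @describeIn informationValues map of a searchlight result.
setMethod("informationValues", "SearchlightResult", function(x) x@D)

setMethod("show", "SearchlightResult", function(object) {
  cat(sprintf("SearchlightResult: %d sources x %d windows (%d estimable)\n",
              nrow(object@D), ncol(object@D), sum(object@ok)))
})
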