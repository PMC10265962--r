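#' @include cvmanova.R
NULL

#' Linear spatial filter (beamformer weights)
#'
#' Unit-gain LCMV weights per source and orientation: for every source
#' `W = (L' C^-1 L)^-1 L' C^-1`, so `W L` is the 3 x 3 identity.
#'
#' @slot weights array `sources x 3 x channels`.
#' @slot hemisphere per-source hemisphere labels.
#' @slot unitGain logical, unit-gain convention flag.
#' @export
setClass("SpatialFilter",
  representation(weights = "array", hemisphere = "character",
                 unitGain = "logical"),
  validity = function(object) {
    d <- dim(object@weights)
    if (length(d) != 3L || d[2L] != 3L)
      return("weights must be sources x 3 x channels")
    if (!all(is.finite(object@weights))) return("weights must be finite")
    TRUE
  })

#' Compute LCMV beamformer weights
#'
#' Linearly constrained minimum-variance spatial filter with unit gain to
#' each source: `W = (L' C^-1 L)^-1 L' C^-1`, with diagonal loading of the
#' sensor covariance (`regularization` times its mean diagonal) for
#' invertibility.
#'
#' @param leadfield a [Leadfield-class].
#' @param dataCovariance `channels x channels` sensor covariance.
#' @param space a [SourceSpace-class] (for hemisphere labels).
#' @param regularization diagonal loading, fraction of the mean sensor
#'   variance (default 0.05).
#' @return a [SpatialFilter-class].
#' @export
lcmvWeights <- function(leadfield, dataCovariance, space,
                        regularization = 0.05) {
  C <- as.matrix(dataCovariance)
  p <- nrow(C)
  Creg <- C + regularization * mean(diag(C)) * diag(p)
  Ci <- tryCatch(chol2inv(chol(Creg)),
                 error = function(e)
                   stop("singular covariance; increase regularization",
                        call. = FALSE))
  g <- leadfield@gain
  nS <- dim(g)[1L]
  W <- array(0, dim = dim(g))
  for (s in seq_len(nS)) {
    L <- t(g[s, , ])                       # channels x 3
    LtCi <- crossprod(L, Ci)               # 3 x channels
    W[s, , ] <- solve(LtCi %*% L, LtCi)
  }
  new("SpatialFilter", weights = W, hemisphere = space@hemisphere,
      unitGain = TRUE)
}

#' Project sensor epochs into source space
#'
#' Applies the spatial filter to every trial.  Without orientation
#' combination the result has three traces per source (ordered
#' source-major); with `combineOrientations = TRUE` the three orientation
#' traces are summed into one per source (the convention used for
#' cross-session decoding).
#'
#' @param epochs sensor-level [EpochArray-class].
#' @param filter a [SpatialFilter-class] for the same channels.
#' @param combineOrientations sum the three orientations per source?
#' @return a source-level [EpochArray-class]; its channel table carries a
#'   `hemisphere` column.
#' @export
projectToSources <- function(epochs, filter, combineOrientations = FALSE) {
  W <- filter@weights
  nS <- dim(W)[1L]
  stopIfNot(dim(W)[3L] == nChannels(epochs),
            "filter channels do not match the epochs")
  Wmat <- matrix(aperm(W, c(2L, 1L, 3L)), nS * 3L, dim(W)[3L])
  d <- epochData(epochs)
  n <- dim(d)[1L]; Tn <- dim(d)[3L]
  if (combineOrientations) {
    comb <- matrix(0, nS, nS * 3L)
    comb[cbind(rep(seq_len(nS), each = 3L),
               seq_len(nS * 3L))] <- 1
    Wmat <- comb %*% Wmat
  }
  out <- array(0, dim = c(n, nrow(Wmat), Tn))
  for (i in seq_len(n)) out[i, , ] <- Wmat %*% d[i, , ]
  chans <- if (combineOrientations)
    data.frame(name = sprintf("SRC%03d", seq_len(nS)),
               x = 0, y = 0, z = 0, hemisphere = filter@hemisphere)
  else
    data.frame(name = sprintf("SRC%03d_o%d", rep(seq_len(nS), each = 3L),
                              rep(1:3, nS)),
               x = 0, y = 0, z = 0,
               hemisphere = rep(filter@hemisphere, each = 3L))
  epochArray(out, samplingRate = samplingRate(epochs),
             tstartMs = timesMs(epochs)[1L], channels = chans,
             trials = trialTable(epochs))
}

#' Default searchlight averaging windows
#'
#' 500-ms windows tiling the two delay periods, with the first 250 ms after
#' each cue excluded from the window directly following it.
#'
#' @param timeline event times, see [taskTimeline()].
#' @return `data.frame` with `label`, `startMs`, `endMs`.
#' @export
searchlightWindows <- function(timeline = taskTimeline()) {
  w1 <- seq(timeline$cue1OffsetMs, timeline$cue2OnsetMs, by = 500)
  w2 <- seq(timeline$cue2OffsetMs, timeline$goOnsetMs, by = 500)
  win <- rbind(data.frame(delay = 1L, startMs = head(w1, -1L),
                          endMs = w1[-1L]),
               data.frame(delay = 2L, startMs = head(w2, -1L),
                          endMs = w2[-1L]))
  win$startMs[c(1L, sum(win$delay == 1L) + 1L)] <-
    win$startMs[c(1L, sum(win$delay == 1L) + 1L)] + 250
  win$label <- sprintf("delay%d_%d", win$delay,
                       stats::ave(win$delay, win$delay, FUN = seq_along))
  win[, c("label", "delay", "startMs", "endMs")]
}

#' Searchlight information mapping
#'
#' Repeats the cross-validated MANOVA on the source level: for every source
#' location, the searchlight channel set is the three dipole directions of
#' the center plus those of its immediate graph neighbors; D is computed
#' per time point and averaged within the given windows.  Locations whose
#' searchlight dimension is too large for the available trials are marked
#' not estimable.
#'
#' @param sourceEpochs orientation-level source [EpochArray-class] from
#'   [projectToSources()] (`combineOrientations = FALSE`).
#' @param space the [SourceSpace-class] providing the neighbor graph.
#' @param contrast a [Contrast-class].
#' @param folds a [FoldScheme-class].
#' @param windows averaging windows (`data.frame` with `startMs`, `endMs`,
#'   `label`), default [searchlightWindows()].
#' @param noiseWindowMs precision-estimation window (ms).
#' @return a [SearchlightResult-class].
#' @export
searchlightInformation <- function(sourceEpochs, space, contrast,
                                   folds = foldScheme(nReps = 2),
                                   windows = searchlightWindows(),
                                   noiseWindowMs = c(taskTimeline()$cue1OffsetMs,
                                                     taskTimeline()$goOnsetMs)) {
  nS <- nrow(space@positions)
  stopIfNot(nChannels(sourceEpochs) == 3L * nS,
            "source epochs must carry 3 orientation traces per source")
  tm <- timesMs(sourceEpochs)
  winIdx <- lapply(seq_len(nrow(windows)), function(i)
    which(tm >= windows$startMs[i] & tm <= windows$endMs[i]))
  D <- matrix(NA_real_, nS, nrow(windows),
              dimnames = list(NULL, windows$label))
  ok <- logical(nS)
  for (s in seq_len(nS)) {
    members <- unique(c(s, space@neighbors[[s]]))
    chIdx <- as.vector(t(outer(members, 1:3,
                               function(m, k) 3L * (m - 1L) + k)))
    sub <- subsetEpochs(sourceEpochs, channels = chIdx)
    res <- tryCatch(cvInformation(sub, contrast, folds, noiseWindowMs),
                    error = function(e) e)
    if (inherits(res, "error")) next
    ok[s] <- TRUE
    v <- informationValues(res)
    D[s, ] <- vapply(winIdx, function(ix) mean(v[ix]), 0)
  }
  new("SearchlightResult", D = D, windows = windows,
      hemisphere = space@hemisphere, ok = ok,
      meta = list(contrast = contrast@variable, folds = folds))
}

#' Lateralization index
#'
#' Mean left-hemisphere information minus mean right-hemisphere
#' information, per window, over estimable searchlight locations.
#'
#' @param result a [SearchlightResult-class].
#' @return named numeric vector, one LI per window.
#' @export
lateralizationIndex <- function(result) {
  h <- result@hemisphere
  useL <- h == "left" & result@ok
  useR <- h == "right" & result@ok
  stopIfNot(any(useL) && any(useR),
            "both hemispheres need estimable searchlights")
  colMeans(result@D[useL, , drop = FALSE]) -
    colMeans(result@D[useR, , drop = FALSE])
}

#' Select an equally spaced source subset
#'
#' Deterministic farthest-point sampling over source positions (e.g. the
#' 229-source subset used for cross-session decoding at full scale).
#'
#' @param space a [SourceSpace-class].
#' @param k subset size.
#' @return sorted integer source indices.
#' @export
selectSourceSubset <- function(space, k) {
  selectSensorSubset(space@positions, k)
}
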