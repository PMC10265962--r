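#' @include source_analysis.R
NULL

## ---------------------------------------------------------------------
## Delay-window averaging, group tests, FDR, visualization smoother.
## ---------------------------------------------------------------------

#' Statistical delay windows
#'
#' Delay 1 runs from 250 ms after the first-cue offset to the second-cue
#' onset; delay 2 from 250 ms after the second-cue offset to the go-cue
#' onset.  The 250-ms exclusions guard against transient cue-evoked
#' responses (the potential glyph confound window).
#'
#' @param timeline event times, see [taskTimeline()].
#' @return `data.frame` with `delay`, `startMs`, `endMs`.
#' @export
delayWindows <- function(timeline = taskTimeline()) {
  data.frame(delay = 1:2,
             startMs = c(timeline$cue1OffsetMs + 250,
                         timeline$cue2OffsetMs + 250),
             endMs = c(timeline$cue2OnsetMs, timeline$goOnsetMs))
}

#' Average information within delay windows
#'
#' @param info an [InformationResult-class] with a per-timepoint vector, or
#'   a numeric vector with a matching time axis.
#' @param windows a window table from [delayWindows()].
#' @param timesMsAxis time axis (ms) when `info` is a plain vector.
#' @return named numeric, one mean per window (`delay1`, `delay2`, ...).
#' @export
averageDelay <- function(info, windows = delayWindows(),
                         timesMsAxis = NULL) {
  if (methods::is(info, "InformationResult")) {
    v <- informationValues(info)
    stopIfNot(!is.matrix(v), "use averageCrossTimeWindow for matrices")
    tm <- info@testTimesMs
  } else {
    v <- info; tm <- timesMsAxis
  }
  out <- vapply(seq_len(nrow(windows)), function(i) {
    idx <- tm >= windows$startMs[i] & tm <= windows$endMs[i]
    stopIfNot(any(idx), "empty delay window")
    mean(v[idx])
  }, 0)
  stats::setNames(out, paste0("delay", windows$delay))
}

#' Average a cross-time matrix over a train/test window pair
#'
#' Mean over the rectangle of training times by test times, excluding cells
#' within `diagonalExclusionMs` of the diagonal (|t_train - t_test| <= 100
#' ms by default).
#'
#' @param info an [InformationResult-class] in cross-time mode, or a matrix.
#' @param trainWindowMs,testWindowMs `c(start, end)` in ms.
#' @param diagonalExclusionMs half-width of the excluded diagonal band.
#' @param trainTimesMs,testTimesMs axes when `info` is a plain matrix.
#' @return scalar mean cross-time information.
#' @export
averageCrossTimeWindow <- function(info, trainWindowMs, testWindowMs,
                                   diagonalExclusionMs = 100,
                                   trainTimesMs = NULL, testTimesMs = NULL) {
  if (methods::is(info, "InformationResult")) {
    m <- informationValues(info)
    trainTimesMs <- info@trainTimesMs
    testTimesMs <- info@testTimesMs
  } else m <- info
  ri <- which(trainTimesMs >= trainWindowMs[1L] &
                trainTimesMs <= trainWindowMs[2L])
  ci <- which(testTimesMs >= testWindowMs[1L] &
                testTimesMs <= testWindowMs[2L])
  stopIfNot(length(ri) > 0 && length(ci) > 0, "windows outside the matrix")
  sub <- m[ri, ci, drop = FALSE]
  keep <- abs(outer(trainTimesMs[ri], testTimesMs[ci], "-")) >
    diagonalExclusionMs
  stopIfNot(any(keep), "all cells excluded by the diagonal band")
  mean(sub[keep])
}

#' One-sample t test against zero
#'
#' @param values per-subject values.
#' @param tail `"greater"`, `"less"` or `"two.sided"`.
#' @return one-row `data.frame`: `n`, `t`, `p_raw`, `tail`.
#' @export
oneSampleT <- function(values, tail = c("greater", "less", "two.sided")) {
  tail <- match.arg(tail)
  stopIfNot(length(values) >= 2, "need at least 2 values")
  stopIfNot(stats::sd(values) > 0, "degenerate sample: zero variance")
  tt <- stats::t.test(values, mu = 0, alternative = tail)
  data.frame(n = length(values), t = unname(tt$statistic),
             p_raw = tt$p.value, tail = tail)
}

#' Paired t test
#'
#' Equivalent to a one-sample t test on the paired differences
#' `valuesA - valuesB`.
#'
#' @param valuesA,valuesB paired per-subject values.
#' @param tail `"greater"`, `"less"` or `"two.sided"` (of A relative to B).
#' @return one-row `data.frame`: `n`, `t`, `p_raw`, `tail`.
#' @export
pairedT <- function(valuesA, valuesB,
                    tail = c("greater", "less", "two.sided")) {
  tail <- match.arg(tail)
  stopIfNot(length(valuesA) == length(valuesB), "unequal lengths")
  d <- valuesA - valuesB
  if (all(d == 0))                      # identical inputs: no evidence either way
    return(data.frame(n = length(d), t = 0,
                      p_raw = if (tail == "two.sided") 1 else 0.5,
                      tail = tail))
  oneSampleT(d, tail)
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up adjusted p-values for the family of tested time intervals;
#' monotone, clipped at 1, idempotent on its own output.
#'
#' @param pvals raw p-values in `[0, 1]`.
#' @return adjusted p-values.
#' @export
fdrBH <- function(pvals) {
  stopIfNot(all(is.finite(pvals)) && all(pvals >= 0 & pvals <= 1),
            "p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Hanning smoothing for visualization
#'
#' Normalized Hann-kernel convolution with full width at half maximum
#' `widthMs` (100 ms by convention), edge-handled by kernel
#' renormalization.  Intended for plotted time courses only; statistics are
#' computed on unsmoothed values.
#'
#' @param series numeric time series.
#' @param widthMs FWHM of the kernel (ms).
#' @param fs sampling rate (Hz).
#' @return smoothed series, same length.
#' @export
hanningSmooth <- function(series, widthMs = 100, fs) {
  w <- max(2L, round(widthMs / 1000 * fs))      # FWHM in samples
  n <- 2L * w - 1L
  kern <- hannWindow(n)
  kern <- kern / sum(kern)
  m <- length(series)
  full <- stats::convolve(c(series, numeric(n)), rev(kern), type = "open")
  norm <- stats::convolve(c(rep(1, m), numeric(n)), rev(kern), type = "open")
  half <- (n - 1L) %/% 2L
  idx <- seq_len(m) + half
  full[idx] / norm[idx]
}
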