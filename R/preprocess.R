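#' @include simulate.R
NULL

## ---------------------------------------------------------------------
## Epoch preprocessing: jump repair, filtering, resampling, baseline,
## vocal-onset detection, trial selection, sensor subsetting.
## ---------------------------------------------------------------------

applyChannelwise <- function(epochs, fun) {
  d <- epochs@data
  for (i in seq_len(dim(d)[1L]))
    for (j in seq_len(dim(d)[2L]))
      d[i, j, ] <- fun(d[i, j, ])
  methods::initialize(epochs, data = d)
}

#' Repair technically caused channel jumps
#'
#' Detects samples whose first difference exceeds `jumpSdFactor` times the
#' robust SD (MAD) of that trace's differences and removes the step by
#' subtracting the offending difference from all subsequent samples.
#' Jump-free traces are returned untouched.
#'
#' @param epochs an [EpochArray-class].
#' @param jumpSdFactor detection threshold in robust SDs (default 20).
#' @return an [EpochArray-class].
#' @export
repairChannelJumps <- function(epochs, jumpSdFactor = 20) {
  stopIfNot(nSamples(epochs) >= 2L, "need at least 2 samples")
  applyChannelwise(epochs, function(x) {
    d <- diff(x)
    s <- stats::mad(d)
    if (s == 0) return(x)
    for (k in which(abs(d) > jumpSdFactor * s))
      x[(k + 1L):length(x)] <- x[(k + 1L):length(x)] - d[k]
    x
  })
}

#' Zero-phase Butterworth low-pass filter
#'
#' Sixth-order (by default) Butterworth IIR low-pass applied forward and
#' backward per channel and trial, giving zero effective phase (the
#' magnitude response is squared).
#'
#' @param epochs an [EpochArray-class].
#' @param cutoffHz cutoff frequency, strictly below Nyquist.
#' @param order filter order (applied in each direction).
#' @return an [EpochArray-class].
#' @export
zeroPhaseLowpass <- function(epochs, cutoffHz, order = 6) {
  fs <- samplingRate(epochs)
  stopIfNot(cutoffHz < fs / 2, "cutoff must be below the Nyquist frequency")
  bf <- signal::butter(order, cutoffHz / (fs / 2), type = "low")
  applyChannelwise(epochs, function(x) {
    ## endpoint detrend + odd-reflection padding: suppresses filtfilt edge
    ## transients and preserves constant (DC) traces exactly
    n <- length(x)
    trend <- x[1L] + (x[n] - x[1L]) * (seq_len(n) - 1L) / max(n - 1L, 1L)
    xc <- x - trend
    L <- min(n - 1L, max(3L * ceiling(fs / cutoffHz), 24L))
    xp <- c(-xc[(L + 1L):2L], xc, -xc[(n - 1L):(n - L)])
    as.numeric(signal::filtfilt(bf, xp))[L + seq_len(n)] + trend
  })
}

#' Anti-aliased resampling
#'
#' Downsamples to `targetHz`: a zero-phase Butterworth anti-alias filter at
#' 45% of the target rate, then interpolation onto a grid anchored at time
#' zero (so cue-locked alignment is preserved to within half a sample).
#' `targetHz` equal to the current rate is the identity.
#'
#' @param epochs an [EpochArray-class].
#' @param targetHz target sampling rate, at most the current rate.
#' @return an [EpochArray-class].
#' @export
resampleTo <- function(epochs, targetHz) {
  fs <- samplingRate(epochs)
  stopIfNot(targetHz <= fs, "upsampling is not supported")
  if (targetHz == fs) return(epochs)
  filtered <- zeroPhaseLowpass(epochs, 0.45 * targetHz)
  told <- timesMs(filtered)
  step <- 1000 / targetHz
  tnew <- seq(ceiling(told[1L] / step), floor(told[length(told)] / step)) * step
  d <- filtered@data
  out <- array(0, dim = c(dim(d)[1L], dim(d)[2L], length(tnew)))
  for (i in seq_len(dim(d)[1L]))
    for (j in seq_len(dim(d)[2L]))
      out[i, j, ] <- stats::approx(told, d[i, j, ], xout = tnew)$y
  epochArray(out, samplingRate = targetHz, tstartMs = tnew[1L],
             channels = filtered@channels, trials = filtered@trials)
}

#' Baseline correction
#'
#' Subtracts, per trial and channel, the mean over the baseline window
#' (default: the 500 ms preceding the first-cue onset).
#'
#' @param epochs an [EpochArray-class].
#' @param windowMs `c(start, end)` in ms relative to cue-1 onset.
#' @return an [EpochArray-class].
#' @export
baselineCorrect <- function(epochs, windowMs = c(-500, 0)) {
  tm <- timesMs(epochs)
  idx <- which(tm >= windowMs[1L] & tm <= windowMs[2L])
  stopIfNot(length(idx) > 0, "baseline window outside the epoch")
  d <- epochs@data
  bl <- apply(d[, , idx, drop = FALSE], c(1L, 2L), mean)
  methods::initialize(epochs, data = d - as.vector(bl))
}

#' Optional independent-component artifact hook
#'
#' Placeholder for biological-artifact removal; synthetic data carry no
#' heartbeat or muscle components, so the default hook is the identity.
#'
#' @param epochs an [EpochArray-class].
#' @param hook a function `EpochArray -> EpochArray` or NULL.
#' @return an [EpochArray-class].
#' @export
icaArtifactHook <- function(epochs, hook = NULL) {
  if (is.null(hook)) epochs else hook(epochs)
}

#' Detect the vocal onset of a trial
#'
#' The audio trace is rectified and smoothed with a median sliding window
#' (42.66 ms); the threshold is the RMS of a 1000-ms segment of a reference
#' imagined trial's envelope plus `thresholdFactor` (default 8) times that
#' segment's SD.  The first threshold crossing after the first-cue onset is
#' reported as the onset, as latency relative to the go cue (negative if the
#' voice started early); no crossing yields `detected = FALSE`.
#'
#' @param wave numeric audio trace of the trial.
#' @param referenceImagined numeric audio trace of an imagined trial
#'   (>= 1000 ms are used as the noise reference).
#' @param fs audio sampling rate (Hz).
#' @param tstartMs time of the first audio sample (ms, cue-1 relative).
#' @param goOnsetMs go-cue time (ms).
#' @param windowMs median-window length (ms).
#' @param thresholdFactor SD multiplier added to the reference RMS.
#' @return list: `latencyMs` (relative to go cue), `detected`, `threshold`.
#' @export
detectVocalOnset <- function(wave, referenceImagined, fs,
                             tstartMs = -500,
                             goOnsetMs = taskTimeline()$goOnsetMs,
                             windowMs = 42.66, thresholdFactor = 8) {
  stopIfNot(length(wave) > 0, "empty audio")
  stopIfNot(length(referenceImagined) >= round(fs),
            "reference segment must cover at least 1000 ms")
  k <- round(windowMs / 1000 * fs)
  if (k %% 2 == 0) k <- k + 1L
  env <- stats::runmed(abs(wave), k)
  refEnv <- stats::runmed(abs(referenceImagined), k)
  seg <- refEnv[seq_len(round(fs))]           # 1000 ms reference period
  thr <- sqrt(mean(seg^2)) + thresholdFactor * stats::sd(seg)
  tMs <- tstartMs + (seq_along(wave) - 1L) * 1000 / fs
  cand <- which(env > thr & tMs >= 0)
  if (!length(cand))
    return(list(latencyMs = NA_real_, detected = FALSE, threshold = thr))
  list(latencyMs = tMs[cand[1L]] - goOnsetMs, detected = TRUE,
       threshold = thr)
}

#' Select analysis-ready trials
#'
#' Keeps trials with the correct production type and, for vocalized trials,
#' the correct vowel and a vocal onset after the go cue.  For sessions whose
#' audio trace is missing (`audio_missing` flag, or onset uniformly `NA`),
#' vowel correctness alone qualifies a vocalized trial.
#'
#' @param trialTable a trial table with columns `production`,
#'   `production_correct`, `vowel_correct`, `vocal_onset_ms`, and optionally
#'   `audio_missing`.
#' @return logical mask over the rows.
#' @export
selectValidTrials <- function(trialTable) {
  need <- c("production", "production_correct", "vowel_correct",
            "vocal_onset_ms")
  miss <- setdiff(need, names(trialTable))
  stopIfNot(length(miss) == 0,
            paste("missing required columns:", paste(miss, collapse = ", ")))
  audioMissing <- if ("audio_missing" %in% names(trialTable))
    trialTable$audio_missing else all(is.na(trialTable$vocal_onset_ms))
  onsetOk <- audioMissing |
    (!is.na(trialTable$vocal_onset_ms) & trialTable$vocal_onset_ms > 0)
  trialTable$production_correct &
    (trialTable$production == "imagined" |
       (trialTable$vowel_correct & onsetOk))
}

#' Select an approximately equally distributed sensor subset
#'
#' Deterministic farthest-point (maximin) sampling over the 3-D sensor
#' positions, seeded at the most superior channel; used to keep the channel
#' count small relative to the trial-count degrees of freedom (137 of 273
#' at full scale).
#'
#' @param positions `n x 3` matrix or `data.frame` with `x`, `y`, `z`.
#' @param k subset size (<= n).
#' @return sorted integer channel indices of length `k`.
#' @export
selectSensorSubset <- function(positions, k) {
  if (is.data.frame(positions))
    positions <- as.matrix(positions[, c("x", "y", "z")])
  n <- nrow(positions)
  stopIfNot(k <= n, "k must not exceed the number of channels")
  if (k == n) return(seq_len(n))
  sel <- integer(k)
  sel[1L] <- which.max(positions[, 3L])
  mind <- rowSums((positions - matrix(positions[sel[1L], ], n, 3L,
                                      byrow = TRUE))^2)
  for (i in seq_len(k - 1L)) {
    sel[i + 1L] <- which.max(mind)
    newd <- rowSums((positions - matrix(positions[sel[i + 1L], ], n, 3L,
                                        byrow = TRUE))^2)
    mind <- pmin(mind, newd)
  }
  sort(sel)
}

#' Standard preprocessing pipeline
#'
#' Composes the stages in their fixed order: jump repair, 30-Hz zero-phase
#' low-pass, resampling to 300 Hz, 10-Hz low-pass, baseline correction on
#' the 500 ms before the first cue.
#'
#' @param epochs an [EpochArray-class].
#' @param lp1Hz first low-pass cutoff (Hz).
#' @param targetHz resampling target (Hz).
#' @param lp2Hz second low-pass cutoff (Hz).
#' @param baselineMs baseline window (ms).
#' @param jumpSdFactor jump-detection threshold (robust SDs).
#' @return an [EpochArray-class].
#' @export
preprocess <- function(epochs, lp1Hz = 30, targetHz = 300, lp2Hz = 10,
                       baselineMs = c(-500, 0), jumpSdFactor = 20) {
  out <- repairChannelJumps(epochs, jumpSdFactor)
  if (lp1Hz < samplingRate(out) / 2) out <- zeroPhaseLowpass(out, lp1Hz)
  out <- resampleTo(out, min(targetHz, samplingRate(out)))
  if (lp2Hz < samplingRate(out) / 2) out <- zeroPhaseLowpass(out, lp2Hz)
  baselineCorrect(out, baselineMs)
}
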