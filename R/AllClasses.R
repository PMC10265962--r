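#' @include AllGenerics.R
NULL

#' Epoched multichannel time series
#'
#' The container every preprocessing and decoding step acts on: a numeric
#' array of `trials x channels x samples`, its sampling rate, the time of the
#' first sample relative to the onset of the first visual cue, channel
#' metadata (name, 3-D position, hemisphere) and the aligned trial table.
#'
#' @slot data numeric array, `trials x channels x samples`; finite.
#' @slot samplingRate sampling rate in Hz.
#' @slot tstartMs time of the first sample (ms, relative to cue-1 onset).
#' @slot channels `data.frame` with columns `name`, `x`, `y`, `z` and
#'   optionally `hemisphere`; one row per channel, names unique.
#' @slot trials `data.frame`, one row per trial (see [trialTable()]).
#' @export
setClass("EpochArray",
  representation(data = "array", samplingRate = "numeric",
                 tstartMs = "numeric", channels = "data.frame",
                 trials = "data.frame"),
  validity = function(object) {
    d <- object@data
    if (length(dim(d)) != 3L) return("data must be trials x channels x samples")
    if (!all(is.finite(d))) return("data must be finite")
    if (nrow(object@trials) != dim(d)[1L])
      return("trial table rows must match the trial axis")
    if (nrow(object@channels) != dim(d)[2L])
      return("channel metadata rows must match the channel axis")
    if (anyDuplicated(object@channels$name)) return("channel names not unique")
    if (object@samplingRate <= 0) return("samplingRate must be positive")
    TRUE
  })

#' One session of the rule-based vocalization task
#'
#' Four rule blocks of 80 trials each (20 per vowel-by-production cell),
#' with a seeded block order and per-block trial shuffles.  Session 2 of a
#' participant reuses session 1's block order reversed.
#'
#' @slot participant participant identifier.
#' @slot session session index, 1 or 2.
#' @slot blockOrder integer permutation of the 4 rules.
#' @slot trials trial table, 320 rows (see [buildSessionDesign()]).
#' @slot seed master seed the design was drawn from.
#' @export
setClass("SessionDesign",
  representation(participant = "character", session = "integer",
                 blockOrder = "integer", trials = "data.frame",
                 seed = "integer"),
  validity = function(object) {
    if (!object@session %in% 1:2) return("session must be 1 or 2")
    if (length(object@blockOrder) != 4L ||
        !setequal(object@blockOrder, 1:4))
      return("blockOrder must be a permutation of 1:4")
    tr <- object@trials
    if (nrow(tr) != 320L) return("a session has 320 trials")
    cnt <- table(tr$block, tr$vowel, tr$production)
    if (!all(cnt == 20L)) return("each block needs 20 trials per cell")
    if (length(unique(tr$condition_id)) != 16L)
      return("a session spans 16 condition codes")
    TRUE
  })

#' Synthetic source space on a spherical shell
#'
#' Quasi-uniform source locations beneath the skull with hemisphere labels,
#' fixed dipole orientations and an immediate-neighbor graph used by the
#' searchlight analysis.
#'
#' @slot positions `n x 3` matrix of locations (m).
#' @slot hemisphere `"left"`/`"right"` per source; counts differ by at most 1.
#' @slot neighbors list of integer vectors, immediate neighbors per source.
#' @slot orientations `n x 3` unit dipole orientation per source.
#' @slot radius shell radius (m).
#' @slot seed seed the geometry was drawn from.
#' @export
setClass("SourceSpace",
  representation(positions = "matrix", hemisphere = "character",
                 neighbors = "list", orientations = "matrix",
                 radius = "numeric", seed = "integer"),
  validity = function(object) {
    n <- nrow(object@positions)
    if (n < 10L) return("need at least 10 sources")
    if (length(object@hemisphere) != n || length(object@neighbors) != n)
      return("per-source metadata lengths must match")
    if (!all(object@hemisphere %in% c("left", "right")))
      return("hemisphere labels must be left/right")
    if (abs(sum(object@hemisphere == "left") -
            sum(object@hemisphere == "right")) > 1L)
      return("hemisphere counts must differ by at most 1")
    if (any(lengths(object@neighbors) < 1L))
      return("every source needs at least one neighbor")
    TRUE
  })

#' Forward gain model from sources to sensors
#'
#' @slot gain numeric array `sources x 3 orientations x channels`.
#' @slot channels `data.frame` of channel name and 3-D position.
#' @slot chanOrient `channels x 3` unit sensitivity direction per channel.
#' @slot decayScale spatial decay scale of the gain (m).
#' @slot seed generation seed.
#' @export
setClass("Leadfield",
  representation(gain = "array", channels = "data.frame",
                 chanOrient = "matrix", decayScale = "numeric",
                 seed = "integer"),
  validity = function(object) {
    d <- dim(object@gain)
    if (length(d) != 3L || d[2L] != 3L)
      return("gain must be sources x 3 x channels")
    if (!all(is.finite(object@gain))) return("gain must be finite")
    if (nrow(object@channels) != d[3L])
      return("channel metadata must match gain")
    TRUE
  })

#' Planted representational structure for the simulator
#'
#' Ground-truth pattern geometry: a stable content axis, an early production
#' axis, a late motor-program component arising once both task variables are
#' known, and a shared effort axis scaled by motor involvement
#' (/u/ > /ə/, vocalized > imagined).  Patterns are unit-norm source
#' vectors, mutually orthogonal unless overlap is requested, with an optional
#' left-hemisphere bias `lambda` and an optional cue-glyph confound.
#'
#' @slot uContent,uProdEarly,uProdLate,uEffort unit source patterns.
#' @slot aContent,aProd,aLate,aEffort amplitudes (source units).
#' @slot effortVowel named numeric `c(u=, schwa=)`, `u > schwa` in effort mode.
#' @slot effortProduction named numeric `c(vocalized=, imagined=)`.
#' @slot tauMs logistic ramp time constant (ms).
#' @slot lambda left-hemisphere mass weight in `[0, 1]` (0.5 = symmetric).
#' @slot aCue cue-glyph confound amplitude (0 disables).
#' @slot cueDriftSd per-block drift of the glyph pattern, relative to `aCue`.
#' @slot seed pattern-drawing seed.
#' @export
setClass("EffectSpec",
  representation(uContent = "numeric", uProdEarly = "numeric",
                 uProdLate = "numeric", uEffort = "numeric",
                 aContent = "numeric", aProd = "numeric",
                 aLate = "numeric", aEffort = "numeric",
                 effortVowel = "numeric", effortProduction = "numeric",
                 tauMs = "numeric", lambda = "numeric",
                 aCue = "numeric", cueDriftSd = "numeric", seed = "integer"),
  validity = function(object) {
    ns <- length(object@uContent)
    if (!all(lengths(list(object@uProdEarly, object@uProdLate,
                          object@uEffort)) == ns))
      return("pattern vectors must share the source dimension")
    for (u in list(object@uContent, object@uProdEarly,
                   object@uProdLate, object@uEffort)) {
      nrm <- sqrt(sum(u^2))
      if (nrm > 0 && abs(nrm - 1) > 1e-8)
        return("pattern vectors must be unit norm (or zero)")
    }
    if (object@lambda < 0 || object@lambda > 1)
      return("lambda must lie in [0, 1]")
    TRUE
  })

#' Sensor and source noise model for the simulator
#'
#' Spatially correlated (random SPD mixing with capped condition number),
#' temporally autocorrelated (AR(1)) sensor noise, per-trial amplitude
#' jitter, small source-level noise, and the session-2 perturbation
#' (channel gain scaling plus a rigid rotation of the source cloud)
#' emulating repositioning between recording sessions.
#'
#' @slot sensorSd marginal sensor noise SD.
#' @slot spatialKappa condition-number cap of the spatial covariance.
#' @slot arPhi AR(1) coefficient, `|phi| < 1`.
#' @slot trialJitterSd SD of the multiplicative per-trial signal jitter.
#' @slot sourceNoiseSd SD of independent source-level noise.
#' @slot session2GainSd SD of per-channel gain scaling in session 2.
#' @slot session2AngleDeg rotation (degrees) of the source cloud in session 2.
#' @slot seed noise-structure seed.
#' @export
setClass("NoiseSpec",
  representation(sensorSd = "numeric", spatialKappa = "numeric",
                 arPhi = "numeric", trialJitterSd = "numeric",
                 sourceNoiseSd = "numeric", session2GainSd = "numeric",
                 session2AngleDeg = "numeric", seed = "integer"),
  validity = function(object) {
    if (abs(object@arPhi) >= 1) return("|arPhi| must be < 1")
    if (object@spatialKappa < 1) return("spatialKappa must be >= 1")
    if (object@sensorSd < 0) return("sensorSd must be non-negative")
    TRUE
  })

#' A simulated recording session
#'
#' @slot epochs sensor-level [EpochArray-class]; trial axis aligned 1:1 with
#'   the design rows.
#' @slot design the [SessionDesign-class] that was simulated.
#' @slot effect ground-truth [EffectSpec-class].
#' @slot noise the [NoiseSpec-class] used.
#' @slot audio per-trial audio waveforms (matrix `trials x samples`) or NULL.
#' @slot audioRate audio sampling rate (Hz).
#' @slot audioTstartMs time of the first audio sample (ms, cue-1 relative).
#' @slot vocalOnsetTruthMs planted vocal onsets (ms after go; NA if imagined).
#' @slot seed simulation seed.
#' @export
setClass("SimulatedDataset",
  representation(epochs = "EpochArray", design = "SessionDesign",
                 effect = "EffectSpec", noise = "NoiseSpec",
                 audio = "ANY", audioRate = "numeric",
                 audioTstartMs = "numeric", vocalOnsetTruthMs = "numeric",
                 seed = "integer"),
  validity = function(object) {
    if (nTrials(object@epochs) != nrow(object@design@trials))
      return("epoch trial axis must align with the design")
    TRUE
  })

#' Condition-space contrast defining a decoded variable
#'
#' A zero-sum weighting over the 16 task conditions (or a subset) selecting
#' which variable is decoded and in which cue-order context.  Only the
#' column space matters to the estimator (a projector is formed), so the
#' scale of the weights is irrelevant.
#'
#' @slot weights `conditions x q` matrix; columns sum to zero over the
#'   included (non-zero) conditions.
#' @slot variable name of the decoded variable.
#' @slot conditions the condition table the weights are indexed by.
#' @export
setClass("Contrast",
  representation(weights = "matrix", variable = "character",
                 conditions = "data.frame"),
  validity = function(object) {
    if (nrow(object@weights) != nrow(object@conditions))
      return("weights must have one row per condition")
    if (any(abs(colSums(object@weights)) > 1e-8))
      return("contrast columns must sum to zero")
    if (all(object@weights == 0)) return("contrast is empty")
    TRUE
  })

#' Cross-validation fold scheme
#'
#' Condition-stratified trial-to-fold assignment: `nReps` independent seeded
#' repetitions of an `nFolds`-fold partition in which every condition is
#' present in every fold.
#'
#' @slot nFolds number of folds (default 5).
#' @slot nReps number of repetitions (default 20).
#' @slot seed assignment seed.
#' @export
setClass("FoldScheme",
  representation(nFolds = "integer", nReps = "integer", seed = "integer"),
  validity = function(object) {
    if (object@nFolds < 2L) return("need at least 2 folds")
    if (object@nReps < 1L) return("need at least 1 repetition")
    TRUE
  })

#' Estimated noise precision (inverse covariance)
#'
#' The bias-corrected precision `(fE - p - 1) (Xi' Xi)^{-1}` estimated from
#' training-set residuals of the delay-window mean.
#'
#' @slot precision symmetric positive-definite `p x p` matrix.
#' @slot fE residual degrees of freedom of the training fit.
#' @slot p number of channels (requires `fE - p - 1 > 0`).
#' @export
setClass("NoisePrecision",
  representation(precision = "matrix", fE = "numeric", p = "numeric"),
  validity = function(object) {
    if (!isTRUE(all.equal(object@precision, t(object@precision),
                          tolerance = 1e-8)))
      return("precision must be symmetric")
    if (object@fE - object@p - 1 <= 0)
      return("insufficient degrees of freedom: fE - p - 1 must be > 0")
    TRUE
  })

#' Time-resolved pattern distinctness
#'
#' Pattern distinctness D per time point (or per train-time x test-time pair
#' for temporal generalization), averaged over folds and repetitions.
#'
#' @slot values numeric vector (per test time) or matrix
#'   (`train times x test times`).
#' @slot trainTimesMs,testTimesMs time axes (ms, cue-1 relative).
#' @slot mode one of `"within"`, `"cross-time"`, `"cross-variable"`,
#'   `"split"`, `"cross-session"`.
#' @slot variable decoded variable (train variable for cross-variable runs).
#' @slot nTest mean number of test trials per fold.
#' @slot meta list: fold scheme, contrasts, splits, seeds.
#' @export
setClass("InformationResult",
  representation(values = "ANY", trainTimesMs = "numeric",
                 testTimesMs = "numeric", mode = "character",
                 variable = "character", nTest = "numeric", meta = "list"),
  validity = function(object) {
    if (!all(is.finite(object@values))) return("D values must be finite")
    TRUE
  })

#' Searchlight information map
#'
#' Pattern distinctness per source location (columns: analysis windows),
#' computed from each source's three dipole directions plus those of its
#' immediate graph neighbors.  Locations whose searchlight dimension is too
#' large for the available trials carry `NA` and `ok = FALSE`.
#'
#' @slot D `sources x windows` matrix of D values (NA where not estimable).
#' @slot windows `data.frame` with `label`, `startMs`, `endMs` per window.
#' @slot hemisphere per-source hemisphere labels.
#' @slot ok logical per source: searchlight estimable.
#' @slot meta list of analysis metadata.
#' @export
setClass("SearchlightResult",
  representation(D = "matrix", windows = "data.frame",
                 hemisphere = "character", ok = "logical", meta = "list"),
  validity = function(object) {
    if (nrow(object@D) != length(object@hemisphere))
      return("hemisphere labels must match the map rows")
    if (length(object@ok) != nrow(object@D))
      return("ok flags must match the map rows")
    if (any(!is.finite(object@D[object@ok, , drop = FALSE])))
      return("estimable locations must carry finite values")
    TRUE
  })
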