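#' @include source_space.R
NULL

## ---------------------------------------------------------------------
## Ground-truth representational structure planted by the simulator.
## ---------------------------------------------------------------------

#' Saturating logistic ramp
#'
#' Activation build-up keyed to a cue: exactly zero before the cue onset,
#' then a logistic rise reaching one half at `tauMs` after the cue and
#' saturating by about `2 tauMs`.
#'
#' @param tMs times (ms).
#' @param onsetMs cue onset (ms).
#' @param tauMs time constant (ms).
#' @return values in `[0, 1)`.
#' @export
rampG <- function(tMs, onsetMs, tauMs = 300) {
  ifelse(tMs < onsetMs, 0,
         stats::plogis((tMs - onsetMs - tauMs) / (tauMs / 4)))
}

#' Specify the planted representational geometry
#'
#' Draws four unit-norm source patterns — a stable content axis, an early
#' production axis, a late motor-program axis and a shared effort axis —
#' mutually orthogonal by construction unless `overlap > 0` mixes the early
#' production axis toward the content axis.  A left-hemisphere weight
#' `lambda` biases pattern mass to the left (`lambda = 1`: all mass left;
#' `0.5`: unbiased).  Effort scalars encode the degree of motor involvement
#' (/u/ above /\eqn{\schwa}/, vocalized above imagined); the shared-axis
#' signal each factor contributes ramps from that factor's own instruction
#' cue, so no variable leaks information before it is cued.
#'
#' Amplitude defaults are the package's calibrated working point: strong
#' enough that a simulated 24-subject cohort at the desk-scale profile
#' reproduces the qualitative significance layout of the within-session
#' analyses, weak enough that null plants stay null (see the methods
#' vignette).
#'
#' @param space a [SourceSpace-class] (patterns live on its sources).
#' @param seed pattern seed.
#' @param aContent,aProd,aLate,aEffort axis amplitudes (source units).
#' @param effortVowel named `c(u=, schwa=)` effort scalars.
#' @param effortProduction named `c(vocalized=, imagined=)` effort scalars.
#' @param tauMs ramp time constant (ms).
#' @param lambda left-hemisphere mass weight in `[0, 1]`.
#' @param overlap in `[0, 1]`: cosine between the early production axis and
#'   the content axis (0 = orthogonal, 1 = identical).
#' @param aCue cue-glyph confound amplitude (sensor units; 0 disables).
#' @param cueDriftSd per-block glyph-pattern drift, relative to `aCue`.
#' @return an [EffectSpec-class].
#' @export
effectSpec <- function(space, seed = 1L,
                       aContent = 1, aProd = 1, aLate = 0.8, aEffort = 1,
                       effortVowel = c(u = 1.3, schwa = 0.7),
                       effortProduction = c(vocalized = 1.3, imagined = 0.7),
                       tauMs = 300, lambda = 0.7, overlap = 0,
                       aCue = 0, cueDriftSd = 0.5) {
  ns <- nrow(space@positions)
  w <- ifelse(space@hemisphere == "left", lambda, 1 - lambda)
  U <- withSeed(deriveSeed(seed, "patterns", ns), {
    raw <- matrix(stats::rnorm(ns * 4L), ns, 4L) * w
    qr.Q(qr(raw))
  })
  normalize <- function(v) {
    n <- sqrt(sum(v^2)); if (n > 0) v / n else v
  }
  uC <- normalize(U[, 1L])
  uPE <- normalize(sqrt(1 - overlap^2) * U[, 2L] + overlap * uC)
  new("EffectSpec",
      uContent = uC, uProdEarly = uPE,
      uProdLate = normalize(U[, 3L]), uEffort = normalize(U[, 4L]),
      aContent = aContent, aProd = aProd, aLate = aLate, aEffort = aEffort,
      effortVowel = effortVowel, effortProduction = effortProduction,
      tauMs = tauMs, lambda = lambda, aCue = aCue, cueDriftSd = cueDriftSd,
      seed = as.integer(seed))
}

#' Specify the noise model
#'
#' @param sensorSd marginal sensor-noise SD (signal amplitudes of order 1
#'   on the planted axes correspond to low single-trial SNR at the default).
#' @param spatialKappa condition-number cap of the random SPD spatial
#'   covariance.
#' @param arPhi AR(1) temporal autocorrelation.
#' @param trialJitterSd SD of the multiplicative per-trial signal jitter.
#' @param sourceNoiseSd SD of independent source-level noise.
#' @param session2GainSd,session2AngleDeg session-2 perturbation (channel
#'   gain scale SD; rigid rotation in degrees).
#' @param seed noise-structure seed.
#' @return a [NoiseSpec-class].
#' @export
noiseSpec <- function(sensorSd = 1, spatialKappa = 10, arPhi = 0.7,
                      trialJitterSd = 0.15, sourceNoiseSd = 0.1,
                      session2GainSd = 0.05, session2AngleDeg = 3,
                      seed = 1L) {
  new("NoiseSpec", sensorSd = sensorSd, spatialKappa = spatialKappa,
      arPhi = arPhi, trialJitterSd = trialJitterSd,
      sourceNoiseSd = sourceNoiseSd, session2GainSd = session2GainSd,
      session2AngleDeg = session2AngleDeg, seed = as.integer(seed))
}

#' Ground-truth source pattern of a condition over time
#'
#' The deterministic part of the simulated source activity:
#' \deqn{m(t) = s_c a_c u_c g_c(t) + s_p a_p u_{pe} g_p(t) +
#'   s_p a_{late} u_{pl} g_2(t) + a_{eff} u_{eff} (e_v(t) e_p(t) - 1)}
#' where `s_c`, `s_p` are +/-1 by vowel and production level, `g_c`/`g_p`
#' are logistic ramps starting at the content/production instruction cue,
#' `g_2` starts at the second cue (once both variables are known), and
#' `e_v(t)`, `e_p(t)` ramp from 1 to the factor's effort scalar after its
#' own cue.  Before the first cue the pattern is exactly zero.
#'
#' @param effect an [EffectSpec-class].
#' @param vowel,production,order trial labels.
#' @param tMs times (ms, cue-1 relative).
#' @param timeline event times, see [taskTimeline()].
#' @return matrix `sources x length(tMs)`.
#' @export
conditionMean <- function(effect, vowel, production, order, tMs,
                          timeline = taskTimeline()) {
  contentOn <- if (order == "content_first") timeline$cue1OnsetMs
               else timeline$cue2OnsetMs
  prodOn <- if (order == "production_first") timeline$cue1OnsetMs
            else timeline$cue2OnsetMs
  tau <- effect@tauMs
  gC <- rampG(tMs, contentOn, tau)
  gP <- rampG(tMs, prodOn, tau)
  gL <- rampG(tMs, timeline$cue2OnsetMs, tau)
  sC <- if (vowel == "u") 1 else -1
  sP <- if (production == "vocalized") 1 else -1
  eV <- 1 + (effect@effortVowel[[vowel]] - 1) * gC
  eP <- 1 + (effect@effortProduction[[production]] - 1) * gP
  outer(effect@uContent, sC * effect@aContent * gC) +
    outer(effect@uProdEarly, sP * effect@aProd * gP) +
    outer(effect@uProdLate, sP * effect@aLate * gL) +
    outer(effect@uEffort, effect@aEffort * (eV * eP - 1))
}
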