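#' @include effects.R
NULL

## ---------------------------------------------------------------------
## Forward simulation of sensor epochs and audio for one session.
## ---------------------------------------------------------------------

## Random SPD spatial mixing with condition number capped at kappa and
## mean eigenvalue 1 (so sensorSd stays the marginal scale).
spatialMixing <- function(nChannels, kappa, seed) {
  withSeed(seed, {
    Q <- qr.Q(qr(matrix(stats::rnorm(nChannels^2), nChannels)))
    ev <- exp(seq(0, log(kappa), length.out = nChannels))
    ev <- ev / mean(ev)
    Q %*% (sqrt(ev) * t(Q))
  })
}

## AR(1) noise, channels x samples, unit marginal SD before mixing.
arNoise <- function(nChannels, nSamples, phi) {
  innov <- matrix(stats::rnorm(nChannels * nSamples, sd = sqrt(1 - phi^2)),
                  nSamples, nChannels)
  t(stats::filter(innov, phi, method = "recursive"))
}

#' Simulate the audio trace of one trial
#'
#' Vocalized trials receive a vocalization burst whose onset is drawn from
#' `N(0.58, 0.12^2)` seconds after the go cue (truncated at 0.05 s);
#' imagined trials carry only a low noise floor that stays below any
#' reasonable envelope threshold.  The sampling rate matches the in-system
#' microphone the onset-detector contract assumes (2343.75 Hz).
#'
#' @param production `"vocalized"` or `"imagined"`.
#' @param seed trial seed.
#' @param fsAudio audio sampling rate (Hz).
#' @param goOnsetMs go-cue time (ms, cue-1 relative).
#' @param tstartMs,tendMs trace extent (ms, cue-1 relative).
#' @param meanOnsetS,sdOnsetS vocal-latency distribution (s after go).
#' @return list: `wave` (numeric vector), `fs`, `tstartMs`,
#'   `onsetMs` (planted onset, ms after go; `NA` for imagined trials).
#' @export
simulateAudio <- function(production, seed = 1L, fsAudio = 2343.75,
                          goOnsetMs = taskTimeline()$goOnsetMs,
                          tstartMs = -500, tendMs = taskTimeline()$trialEndMs,
                          meanOnsetS = 0.58, sdOnsetS = 0.12) {
  n <- floor((tendMs - tstartMs) / 1000 * fsAudio) + 1L
  tMs <- tstartMs + (seq_len(n) - 1L) * 1000 / fsAudio
  withSeed(seed, {
    wave <- stats::rnorm(n, sd = 0.005)
    onsetMs <- NA_real_
    if (production == "vocalized") {
      onsetMs <- max(50, stats::rnorm(1L, meanOnsetS, sdOnsetS) * 1000)
      t0 <- goOnsetMs + onsetMs
      idx <- tMs >= t0 & tMs <= t0 + 600
      rise <- pmin(1, (tMs[idx] - t0) / 10)
      wave[idx] <- wave[idx] +
        rise * (0.8 + 0.2 * sin(2 * pi * 220 * tMs[idx] / 1000)) *
          stats::rnorm(sum(idx), sd = 0.3) +
        rise * 0.6 * sin(2 * pi * 150 * (tMs[idx] - t0) / 1000)
    }
    list(wave = wave, fs = fsAudio, tstartMs = tstartMs, onsetMs = onsetMs)
  })
}

#' Simulate one MEG session
#'
#' Per trial, source activity is the ground-truth [conditionMean()] plus
#' independent source noise; sensor data are the leadfield projection plus
#' spatially correlated, temporally autocorrelated sensor noise, with a
#' multiplicative per-trial signal jitter.  For a session-2 design the
#' leadfield is perturbed (gain scaling and a rigid rotation of the source
#' cloud) to emulate head repositioning.  If the effect specifies a
#' cue-glyph confound (`aCue > 0`), an additive glyph-locked sensor pattern
#' (identical across the glyph's possible meanings, with an independent
#' per-block drift) is injected during the 250 ms after each cue onset.
#'
#' @param design a [SessionDesign-class].
#' @param effect an [EffectSpec-class] on `space`'s sources.
#' @param noise a [NoiseSpec-class].
#' @param leadfield the session-1 [Leadfield-class] for `space`.
#' @param space the [SourceSpace-class].
#' @param seed simulation seed.
#' @param fs sensor sampling rate (Hz).
#' @param tstartMs,tendMs epoch extent (ms, cue-1 relative).
#' @param audio simulate per-trial audio traces?
#' @return a [SimulatedDataset-class].
#' @examples
#' sp <- makeSourceSpace(20, seed = 1)
#' lf <- makeLeadfield(sp, 12, seed = 1)
#' des <- buildSessionDesign("P01", 1, seed = 7)
#' sim <- simulateSession(des, effectSpec(sp), noiseSpec(), lf, sp,
#'                        seed = 7, fs = 40, tendMs = 500)
#' sim
#' @export
simulateSession <- function(design, effect, noise, leadfield, space, seed,
                            fs = 300, tstartMs = -500, tendMs = 4500,
                            audio = FALSE) {
  stopIfNot(length(effect@uContent) == nrow(space@positions),
            "effect patterns and source space disagree in size")
  stopIfNot(dim(leadfield@gain)[1L] == nrow(space@positions),
            "leadfield and source space disagree in size")
  trials <- design@trials
  tl <- taskTimeline()
  nT <- floor((tendMs - tstartMs) / 1000 * fs) + 1L
  tMs <- tstartMs + (seq_len(nT) - 1L) * 1000 / fs
  lf <- leadfield
  if (design@session == 2L)
    lf <- perturbLeadfield(leadfield, space, noise@session2GainSd,
                           noise@session2AngleDeg,
                           deriveSeed(seed, "s2", design@participant))
  L <- collapseLeadfield(lf, space)          # sources x channels
  nCh <- ncol(L)

  ## deterministic sensor-level mean time course per condition
  ct <- conditionTable()
  meanByCond <- lapply(seq_len(nrow(ct)), function(i)
    crossprod(L, conditionMean(effect, ct$vowel[i], ct$production[i],
                               ct$order[i], tMs, tl)))  # channels x time

  A <- spatialMixing(nCh, noise@spatialKappa, deriveSeed(noise@seed, "mix", nCh))

  ## cue-glyph confound patterns (sensor level)
  cueOn <- c(tl$cue1OnsetMs, tl$cue2OnsetMs)
  useCue <- effect@aCue > 0
  if (useCue) {
    base <- withSeed(deriveSeed(effect@seed, "cue-base", nCh), {
      b <- matrix(stats::rnorm(2L * nCh), nCh, 2L,
                  dimnames = list(NULL, c("forward_slash", "backward_slash")))
      sweep(b, 2L, sqrt(colSums(b^2)), "/")
    })
    bump <- lapply(cueOn, function(on) {
      idx <- which(tMs >= on & tMs <= on + 250)
      w <- numeric(nT)
      if (length(idx)) w[idx] <- hannWindow(length(idx))
      w
    })
  }

  dat <- array(0, dim = c(nrow(trials), nCh, nT))
  withSeed(deriveSeed(seed, "noise", design@participant, design@session), {
    jit <- 1 + stats::rnorm(nrow(trials), sd = noise@trialJitterSd)
    for (i in seq_len(nrow(trials))) {
      x <- jit[i] * meanByCond[[trials$condition_id[i]]]
      if (noise@sourceNoiseSd > 0)
        x <- x + crossprod(L, matrix(
          stats::rnorm(nrow(L) * nT, sd = noise@sourceNoiseSd), nrow(L), nT))
      x <- x + noise@sensorSd * (A %*% arNoise(nCh, nT, noise@arPhi))
      if (useCue) {
        for (ci in 1:2) {
          glyph <- trials[[c("cue1_glyph", "cue2_glyph")[ci]]][i]
          drift <- withSeed(deriveSeed(seed, "cue-drift", design@session,
                                       trials$block[i], glyph, ci),
                            stats::rnorm(nCh))
          drift <- drift / sqrt(sum(drift^2))
          pat <- effect@aCue *
            (base[, glyph] + effect@cueDriftSd * drift)
          x <- x + outer(pat, bump[[ci]])
        }
      }
      dat[i, , ] <- x
    }
  })

  audioMat <- NULL; audioRate <- 0; audioT0 <- 0
  onsets <- rep(NA_real_, nrow(trials))
  if (audio) {
    aud <- lapply(seq_len(nrow(trials)), function(i)
      simulateAudio(trials$production[i],
                    seed = deriveSeed(seed, "audio", design@session, i)))
    audioMat <- do.call(rbind, lapply(aud, `[[`, "wave"))
    audioRate <- aud[[1L]]$fs
    audioT0 <- aud[[1L]]$tstartMs
    onsets <- vapply(aud, `[[`, 0, "onsetMs")
  }

  epochs <- epochArray(dat, samplingRate = fs, tstartMs = tstartMs,
                       channels = lf@channels, trials = trials)
  new("SimulatedDataset", epochs = epochs, design = design, effect = effect,
      noise = noise, audio = audioMat, audioRate = audioRate,
      audioTstartMs = audioT0, vocalOnsetTruthMs = onsets,
      seed = as.integer(seed))
}
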