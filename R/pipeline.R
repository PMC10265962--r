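#' @include group_stats.R
NULL

## ---------------------------------------------------------------------
## End-to-end orchestration: simulate -> (preprocess) -> decode -> stats.
## ---------------------------------------------------------------------

#' Build an experiment configuration
#'
#' Defaults mirror the study conditions: 24 subjects, two sessions of 320
#' trials, fivefold cross-validation with 20 repetitions.  The default
#' dimensional profile is the desk-scale working point (64 channels, 60
#' sources, 300 Hz); the full-scale geometry (273 channels with a
#' 137-sensor analysis subset, 457 sources) is available by overriding
#' `profile`.
#'
#' @param nSubjects number of simulated participants.
#' @param profile list: `nChannels`, `nSources`, `fs`, `tstartMs`,
#'   `tendMs`, optional `sensorSubset` (channel count kept for decoding).
#' @param effectArgs arguments for [effectSpec()] (amplitudes etc.).
#' @param noiseArgs arguments for [noiseSpec()].
#' @param folds list: `nFolds`, `nReps`.
#' @param orders cue orders analysed.
#' @param analyses subset of `c("within", "searchlight")`.
#' @param preprocess run the filtering/baseline pipeline before decoding?
#' @param seed master seed; every stream derives from it.
#' @return a config list (class `"vocalinfoConfig"`).
#' @export
experimentConfig <- function(nSubjects = 24,
                             profile = list(nChannels = 64, nSources = 60,
                                            fs = 300, tstartMs = -500,
                                            tendMs = 4500,
                                            sensorSubset = NULL),
                             effectArgs = list(), noiseArgs = list(),
                             folds = list(nFolds = 5, nReps = 20),
                             orders = c("content_first", "production_first"),
                             analyses = "within",
                             preprocess = FALSE, seed = 1L) {
  cfg <- list(nSubjects = nSubjects, profile = profile,
              effectArgs = effectArgs, noiseArgs = noiseArgs,
              folds = folds, orders = orders, analyses = analyses,
              preprocess = preprocess, seed = as.integer(seed))
  class(cfg) <- "vocalinfoConfig"
  cfg
}

#' Simulate one participant (both sessions)
#'
#' Shares the source space, leadfield geometry, and planted effect across
#' the participant's two sessions; session 2 receives the reversed block
#' order and the session-2 leadfield perturbation.
#'
#' @param participant participant identifier.
#' @param config an [experimentConfig()] list.
#' @param sessions which sessions to simulate.
#' @param audio simulate audio traces?
#' @return list of [SimulatedDataset-class], one per session.
#' @export
simulateParticipant <- function(participant, config, sessions = 1:2,
                                audio = FALSE) {
  pr <- config$profile
  space <- makeSourceSpace(pr$nSources,
                           seed = deriveSeed(config$seed, "space"))
  lf <- makeLeadfield(space, pr$nChannels,
                      seed = deriveSeed(config$seed, "leadfield"))
  effect <- do.call(effectSpec, c(
    list(space = space, seed = deriveSeed(config$seed, "effect", participant)),
    config$effectArgs))
  noise <- do.call(noiseSpec, c(
    list(seed = deriveSeed(config$seed, "noise", participant)),
    config$noiseArgs))
  lapply(sessions, function(ss) {
    des <- buildSessionDesign(participant, ss,
                              deriveSeed(config$seed, "design", participant))
    simulateSession(des, effect, noise, lf, space,
                    seed = deriveSeed(config$seed, "sim", participant, ss),
                    fs = pr$fs, tstartMs = pr$tstartMs, tendMs = pr$tendMs,
                    audio = audio)
  })
}

## Analysis-ready epochs for one simulated session: optional preprocessing
## and sensor subsetting, valid-trial selection.
prepareEpochs <- function(dataset, config) {
  ep <- dataset@epochs
  if (isTRUE(config$preprocess))
    ep <- preprocess(ep, targetHz = min(samplingRate(ep), 300))
  else
    ep <- baselineCorrect(ep)
  k <- config$profile$sensorSubset
  if (!is.null(k) && k < nChannels(ep))
    ep <- subsetEpochs(ep, channels = selectSensorSubset(channelInfo(ep), k))
  keep <- selectValidTrials(trialTable(ep))
  subsetEpochs(ep, trials = which(keep))
}

## Session-averaged delay-window information for one subject and variable.
subjectDelayInfo <- function(epochsList, variable, order, folds) {
  con <- makeContrast(variable, orders = order)
  d <- lapply(epochsList, function(ep)
    averageDelay(cvInformation(ep, con, folds)))
  Reduce(`+`, d) / length(d)
}

#' Run a full simulated experiment
#'
#' For each simulated participant: generate both sessions, prepare the
#' epochs, compute within-session delay-window information per variable and
#' cue order (sessions averaged at the D level), then group one-tailed
#' t tests with FDR correction over the tested intervals of each cue-order
#' analysis.  Only intervals in which the variable is in principle known to
#' the participant are tested.  Fully reproducible from the config seed.
#'
#' @param config an [experimentConfig()] list.
#' @param verbose print per-subject progress?
#' @return list: `config`, `hash`, `info` (per-subject delay table),
#'   `stats` (group table with `p_fdr`), optionally `lateralization`, and
#'   `sequentialPattern` — TRUE when the content-first analysis shows content
#'   information in both delays but production information only in delay 2.
#' @export
runExperiment <- function(config = experimentConfig(), verbose = FALSE) {
  folds <- foldScheme(config$folds$nFolds, config$folds$nReps,
                      seed = deriveSeed(config$seed, "folds"))
  rows <- list(); li <- list()
  for (s in seq_len(config$nSubjects)) {
    pid <- sprintf("S%02d", s)
    sims <- simulateParticipant(pid, config)
    eps <- lapply(sims, prepareEpochs, config = config)
    for (variable in c("content", "production"))
      for (ord in config$orders) {
        dv <- subjectDelayInfo(eps, variable, ord, folds)
        rows[[length(rows) + 1L]] <- data.frame(
          subject = pid, variable = variable, order = ord,
          delay = 1:2, D = unname(dv))
      }
    if ("searchlight" %in% config$analyses)
      li[[pid]] <- subjectLateralization(sims[[1L]], config, folds)
    if (verbose) message("subject ", pid, " done")
  }
  info <- do.call(rbind, rows)

  ## group tests: intervals where the variable could be known
  tested <- expand.grid(variable = c("content", "production"),
                        order = config$orders, delay = 1:2,
                        stringsAsFactors = FALSE)
  known <- with(tested, delay == 2L |
                  (variable == "content" & order == "content_first") |
                  (variable == "production" & order == "production_first"))
  tested <- tested[known, ]
  stats <- do.call(rbind, lapply(seq_len(nrow(tested)), function(i) {
    v <- info$D[info$variable == tested$variable[i] &
                  info$order == tested$order[i] &
                  info$delay == tested$delay[i]]
    cbind(tested[i, ], oneSampleT(v, "greater"),
          family = tested$order[i])
  }))
  stats$p_fdr <- stats::ave(stats$p_raw, stats$family, FUN = fdrBH)
  rownames(stats) <- NULL

  seqPat <- NA
  if ("content_first" %in% config$orders) {
    sig <- function(variable, delay) {
      r <- stats[stats$variable == variable &
                   stats$order == "content_first" & stats$delay == delay, ]
      nrow(r) == 1L && r$p_fdr < 0.05
    }
    pd1 <- info$D[info$variable == "production" &
                    info$order == "content_first" & info$delay == 1L]
    pd1t <- oneSampleT(pd1, "greater")       # untested interval, checked here
    seqPat <- sig("content", 1L) && sig("content", 2L) && sig("production", 2L) &&
      pd1t$p_raw >= 0.05
  }

  out <- list(config = config, hash = contentHash(config), info = info,
              stats = stats, sequentialPattern = seqPat)
  if (length(li)) out$lateralization <- do.call(rbind, li)
  out
}

#' Per-subject structure-recovery metrics for a simulated cohort
#'
#' For every simulated participant (session 1, prepared epochs), computes
#' the quantities the representational analyses rest on: within-delay and
#' between-delay cross-time information for both variables (diagonal
#' band +/- 100 ms excluded) with the expected-stable benchmark,
#' cross-variable information in the relevant-cue-first configuration and
#' within the content-first order with its expected value, and the
#' split-condition delay-2 information (content by production type,
#' production by vowel, content-first order).
#'
#' @param config an [experimentConfig()] list.
#' @param verbose print per-subject progress?
#' @return `data.frame`, one row per subject.
#' @export
cohortStructureMetrics <- function(config, verbose = FALSE) {
  folds <- foldScheme(config$folds$nFolds, config$folds$nReps,
                      seed = deriveSeed(config$seed, "folds"))
  d1w <- unlist(delayWindows()[1L, c("startMs", "endMs")])
  d2w <- unlist(delayWindows()[2L, c("startMs", "endMs")])
  rows <- lapply(seq_len(config$nSubjects), function(s) {
    pid <- sprintf("S%02d", s)
    sims <- simulateParticipant(pid, config, sessions = 1)
    ep <- prepareEpochs(sims[[1L]], config)
    tm <- timesMs(ep)
    del2 <- tm >= d2w[1L] & tm <= d2w[2L]
    ctWin <- function(info, a, b)
      averageCrossTimeWindow(info, a, b)
    crossBlock <- function(variable, order) {
      m <- crossTimeInformation(ep, makeContrast(variable, orders = order),
                                folds)
      c(within1 = ctWin(m, d1w, d1w), within2 = ctWin(m, d2w, d2w),
        between = (ctWin(m, d1w, d2w) + ctWin(m, d2w, d1w)) / 2)
    }
    prodCt <- crossBlock("production", "production_first")
    contCt <- crossBlock("content", "content_first")
    ## cross-variable: relevant cue first (mixed orders), and content-first
    cvRel <- crossVariableInformation(
      ep, makeContrast("content", orders = "content_first"),
      makeContrast("production", orders = "production_first"), folds)
    vRel <- informationValues(cvRel)
    del1 <- tm >= d1w[1L] & tm <= d1w[2L]
    cvCF <- crossVariableInformation(
      ep, makeContrast("content", orders = "content_first"),
      makeContrast("production", orders = "content_first"), folds)
    vCF <- informationValues(cvCF)
    Dc <- averageDelay(cvInformation(ep, makeContrast("content",
                                                      orders = "content_first"),
                                     folds))
    Dp <- averageDelay(cvInformation(ep, makeContrast("production",
                                                      orders = "content_first"),
                                     folds))
    splitD2 <- function(variable, splitVariable, splitLevel) {
      v <- informationValues(splitConditionInformation(
        ep, makeContrast(variable, orders = "content_first"),
        splitVariable, splitLevel, folds))
      mean(v[del2])
    }
    if (verbose) message("subject ", pid, " done")
    data.frame(subject = pid,
               prodCt1 = prodCt[["within1"]], prodCt2 = prodCt[["within2"]],
               prodCtBetween = prodCt[["between"]],
               contCt1 = contCt[["within1"]], contCt2 = contCt[["within2"]],
               contCtBetween = contCt[["between"]],
               cvRelFirstDelay1 = mean(vRel[del1]),
               cvContentFirstDelay2 = mean(vCF[del2]),
               DcDelay2 = Dc[["delay2"]], DpDelay2 = Dp[["delay2"]],
               splitContentVocalized = splitD2("content", "production",
                                               "vocalized"),
               splitContentImagined = splitD2("content", "production",
                                              "imagined"),
               splitProductionU = splitD2("production", "vowel", "u"),
               splitProductionSchwa = splitD2("production", "vowel", "schwa"))
  })
  do.call(rbind, rows)
}

## Per-subject searchlight lateralization of both variables (session 1).
subjectLateralization <- function(dataset, config, folds,
                                  windows = searchlightWindows()) {
  space <- makeSourceSpace(config$profile$nSources,
                           seed = deriveSeed(config$seed, "space"))
  lf <- makeLeadfield(space, config$profile$nChannels,
                      seed = deriveSeed(config$seed, "leadfield"))
  ep <- baselineCorrect(dataset@epochs)
  ## sensor covariance over all trials and samples
  X <- apply(epochData(ep), 2L, as.vector)
  C <- stats::cov(X)
  filt <- lcmvWeights(lf, C, space)
  src <- projectToSources(ep, filt)
  slFolds <- foldScheme(folds@nFolds, min(2L, folds@nReps), folds@seed)
  out <- lapply(c("content", "production"), function(variable) {
    sl <- searchlightInformation(src, space, makeContrast(variable),
                                 folds = slFolds, windows = windows)
    data.frame(subject = dataset@design@participant, variable = variable,
               window = sl@windows$label, LI = unname(lateralizationIndex(sl)))
  })
  do.call(rbind, out)
}
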