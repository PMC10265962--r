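#' @include contrasts.R
NULL

## ---------------------------------------------------------------------
## Cross-validated MANOVA: pattern distinctness and its cross-decoding
## variants (time, variable, condition split, session).
## ---------------------------------------------------------------------

#' Cross-validation fold scheme
#'
#' @param nFolds folds per repetition (default 5).
#' @param nReps repetitions (default 20); folds and repetitions are
#'   averaged.
#' @param seed assignment seed.
#' @return a [FoldScheme-class].
#' @export
foldScheme <- function(nFolds = 5, nReps = 20, seed = 1L) {
  new("FoldScheme", nFolds = as.integer(nFolds), nReps = as.integer(nReps),
      seed = as.integer(seed))
}

## Condition-stratified fold assignment: every condition in every fold.
stratifiedFolds <- function(cond, nFolds, seed) {
  cnt <- table(cond)
  if (any(cnt < nFolds))
    stop("stratification error: condition ", names(cnt)[which.min(cnt)],
         " has fewer trials than folds", call. = FALSE)
  assign <- integer(length(cond))
  withSeed(seed, {
    for (lv in names(cnt)) {
      idx <- sample(which(cond == lv))
      assign[idx] <- rep_len(seq_len(nFolds), length(idx))
    }
  })
  lapply(seq_len(nFolds), function(f)
    list(train = which(assign != f), test = which(assign == f)))
}

#' Least-squares condition means
#'
#' `B = X^+ Y`: the multivariate general-linear-model solution; for an
#' indicator design this is the matrix of per-condition channel means.
#'
#' @param X design matrix `trials x conditions` (full column rank on the
#'   included conditions).
#' @param Y data matrix `trials x channels`.
#' @return `conditions x channels` coefficient matrix.
#' @export
fitConditionMeans <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  empty <- colSums(X != 0) == 0
  if (any(empty))
    stop("design is rank deficient: condition ",
         paste(which(empty), collapse = ", "), " has no trials",
         call. = FALSE)
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("design matrix is rank deficient", call. = FALSE)
  qr.coef(qrX, Y)
}

#' Estimate the noise precision from training residuals
#'
#' Residuals `Xi = Y - X B` of the delay-window-mean data give the
#' bias-corrected precision `Sigma^-1 = (fE - p - 1) (Xi' Xi)^-1` with
#' `fE = n - rank(X)`.  Requires `fE - p - 1 > 0`, which is why sensor-level
#' analyses run on a spatial channel subset.
#'
#' @param X training design matrix.
#' @param Ytw training data averaged over the noise window
#'   (`trials x channels`).
#' @return a [NoisePrecision-class].
#' @export
estimateNoisePrecision <- function(X, Ytw) {
  X <- as.matrix(X); Ytw <- as.matrix(Ytw)
  p <- ncol(Ytw)
  fE <- nrow(X) - qr(X)$rank
  if (fE - p - 1 <= 0)
    stop("insufficient trials for channel count: fE - p - 1 = ",
         fE - p - 1, call. = FALSE)
  B <- fitConditionMeans(X, Ytw)
  Xi <- Ytw - X %*% B
  prec <- (fE - p - 1) * chol2inv(chol(crossprod(Xi)))
  new("NoisePrecision", precision = (prec + t(prec)) / 2, fE = fE, p = p)
}

#' Cross-validated pattern distinctness (one train/test instance)
#'
#' The core statistic:
#' \deqn{D = \frac{1}{n}\,\mathrm{tr}\!\left(B_{train}' C_{train}
#'   (C_{train}'C_{train})^{+}\,[C_{train}' X_{test}'X_{test} C_{train}]\,
#'   (C_{test}'C_{test})^{+} C_{test}' B_{test}\,\Sigma^{-1}\right)}
#' the noise-normalized channel-space inner product of the train-contrast
#' and test-contrast coefficient patterns, with the test design's
#' cross-product entering through the training contrast.  When
#' `Ctrain = Ctest` this reduces exactly to the contrast-subspace projector
#' form `tr(B' P X'X P B Sigma^-1)/n` with `P = C (C'C)^+ C'`.  D is
#' invariant to the contrast scales and to any fixed invertible channel
#' mixing of all data, and cross-validated so its expectation is zero in
#' the absence of a true effect (sampling noise can make it negative).
#'
#' @param Btrain,Btest `conditions x channels` coefficients from independent
#'   data splits.
#' @param Ctrain,Ctest zero-sum contrast vectors/matrices over conditions.
#' @param XtXtest `conditions x conditions` cross-product of the test design
#'   (diagonal condition counts for an indicator design).
#' @param sigmaInv a [NoisePrecision-class] or precision matrix.
#' @param nTest number of test trials.
#' @return scalar D.
#' @export
patternDistinctness <- function(Btrain, Btest, Ctrain, Ctest, XtXtest,
                                sigmaInv, nTest) {
  if (methods::is(sigmaInv, "NoisePrecision")) sigmaInv <- sigmaInv@precision
  Btrain <- as.matrix(Btrain); Btest <- as.matrix(Btest)
  stopIfNot(nrow(Btrain) == nrow(Btest) &&
              ncol(Btrain) == ncol(Btest) &&
              ncol(Btrain) == nrow(sigmaInv),
            "non-conformable inputs")
  if (!is.matrix(Ctrain)) Ctrain <- matrix(Ctrain, ncol = 1L)
  if (!is.matrix(Ctest)) Ctest <- matrix(Ctest, ncol = 1L)
  Wtr <- Ctrain %*% pinv(crossprod(Ctrain))      # K x q
  Wte <- Ctest %*% pinv(crossprod(Ctest))
  M <- crossprod(Ctrain, XtXtest %*% Ctrain)     # q x q
  U <- crossprod(Wtr, Btrain)                    # q x p
  V <- M %*% crossprod(Wte, Btest) %*% sigmaInv  # q x p
  sum(U * V) / nTest
}

## ---------------------------------------------------------------------
## Engine shared by all decoding variants.
##
## Y:        trials x channels x time array
## cond:     integer condition codes (indexed into condition table rows)
## K:        number of condition levels
## Ctr, Cte: contrast matrices (K x q)
## folds:    list of list(train, test) index sets
## noiseIdx: sample indices averaged for the precision estimate
## testMask: logical over trials restricting the test side (splits)
## crossTime: return the full train-time x test-time matrix?
## testCond: condition rows that must be present in every test set
## ---------------------------------------------------------------------
cvEngine <- function(Y, cond, K, Ctr, Cte, folds, noiseIdx,
                     testMask = NULL, crossTime = FALSE, testCond = NULL) {
  if (!is.matrix(Ctr)) Ctr <- matrix(Ctr, ncol = 1L)
  if (!is.matrix(Cte)) Cte <- matrix(Cte, ncol = 1L)
  q <- ncol(Ctr)
  stopIfNot(ncol(Cte) == q, "train and test contrasts must share rank")
  Wtr <- t(Ctr %*% pinv(crossprod(Ctr)))         # q x K
  Wte <- t(Cte %*% pinv(crossprod(Cte)))         # q x K
  dims <- dim(Y)
  n <- dims[1L]; p <- dims[2L]; Tn <- dims[3L]
  acc <- NULL; nTestAcc <- 0
  for (fold in folds) {
    tr <- fold$train
    te <- fold$test
    if (!is.null(testMask)) te <- te[testMask[te]]
    cntTr <- tabulate(cond[tr], nbins = K)
    if (any(cntTr == 0))
      stop("stratification error: condition ", which(cntTr == 0)[1L],
           " absent from a training set", call. = FALSE)
    cntTe <- tabulate(cond[te], nbins = K)
    if (!is.null(testCond) && any(cntTe[testCond] == 0))
      stop("split level absent from a test fold", call. = FALSE)

    ## noise precision from the window mean of the training set
    Ytr <- Y[tr, , , drop = FALSE]
    nw <- length(noiseIdx)
    tmp <- Ytr[, , noiseIdx, drop = FALSE]
    dim(tmp) <- c(length(tr) * p, nw)
    Ytw <- matrix(tmp %*% rep(1 / nw, nw), length(tr), p)
    Btw <- rowsum(Ytw, cond[tr]) / cntTr[sort(unique(cond[tr]))]
    Xi <- Ytw - Btw[match(cond[tr], sort(unique(cond[tr]))), , drop = FALSE]
    fE <- length(tr) - sum(cntTr > 0)
    if (fE - p - 1 <= 0)
      stop("insufficient trials for channel count: fE - p - 1 = ",
           fE - p - 1, call. = FALSE)
    S <- (fE - p - 1) * chol2inv(chol(crossprod(Xi)))

    ## per-timepoint condition means, train and test
    Btr <- condMeansArray(Ytr, cond[tr], K, cntTr)         # K x p x T
    Bte <- condMeansArray(Y[te, , , drop = FALSE], cond[te], K, cntTe)

    ## U_t = (C (C'C)+)' B_t ; V_t = [C_tr' X'X C_tr] (C'C)+ C_te' B_t S
    M <- crossprod(Ctr, Ctr * cntTe)                       # q x q
    U <- flattenTP(tensorCondMult(Wtr, Btr), q, p, Tn)
    Vm <- flattenTP(tensorCondMult(M %*% Wte, Bte), q, p, Tn)
    ## apply Sigma^-1 on the channel axis
    dim(Vm) <- c(Tn * q, p)
    Vm <- Vm %*% S
    dim(Vm) <- c(Tn, q * p)
    dim(U) <- c(Tn, q * p)

    nTest <- length(te)
    D <- if (crossTime) (U %*% t(Vm)) / nTest
         else rowSums(U * Vm) / nTest
    acc <- if (is.null(acc)) D else acc + D
    nTestAcc <- nTestAcc + nTest
  }
  list(D = acc / length(folds), nTest = nTestAcc / length(folds))
}

## K x p x T condition means; conditions with no trials get zero rows.
condMeansArray <- function(Y, cond, K, cnt) {
  d <- dim(Y)
  dim(Y) <- c(d[1L], d[2L] * d[3L])
  B <- matrix(0, K, d[2L] * d[3L])
  rs <- rowsum(Y, cond)
  lev <- as.integer(rownames(rs))
  B[lev, ] <- rs / cnt[lev]
  dim(B) <- c(K, d[2L], d[3L])
  B
}

## multiply a q x K matrix onto the condition axis of a K x p x T tensor
tensorCondMult <- function(M, B) {
  d <- dim(B)
  dim(B) <- c(d[1L], d[2L] * d[3L])
  out <- M %*% B
  dim(out) <- c(nrow(M), d[2L], d[3L])
  out
}

## reorder K x p x T to T x (K, p) rows-by-time
flattenTP <- function(B, K, p, Tn) {
  out <- aperm(B, c(3L, 1L, 2L))
  dim(out) <- c(Tn, K * p)
  out
}

## shared setup: extract Y, condition indices, projectors, noise window
decodeSetup <- function(epochs, contrastTrain, contrastTest, noiseWindowMs) {
  ct <- contrastTrain@conditions
  cond <- match(trialTable(epochs)$condition_id, ct$condition_id)
  stopIfNot(!anyNA(cond), "trials carry condition codes outside the contrast table")
  tm <- timesMs(epochs)
  noiseIdx <- which(tm >= noiseWindowMs[1L] & tm <= noiseWindowMs[2L])
  stopIfNot(length(noiseIdx) > 0, "noise window outside the epoch")
  list(Y = epochData(epochs), cond = cond, K = nrow(ct), tm = tm,
       noiseIdx = noiseIdx,
       Ctr = contrastTrain@weights, Cte = contrastTest@weights)
}

runRepetitions <- function(setup, folds, testMask = NULL, crossTime = FALSE,
                           testCond = NULL) {
  acc <- NULL; nT <- 0
  for (r in seq_len(folds@nReps)) {
    fl <- stratifiedFolds(setup$cond, folds@nFolds,
                          deriveSeed(folds@seed, "rep", r))
    res <- cvEngine(setup$Y, setup$cond, setup$K, setup$Ctr, setup$Cte, fl,
                    setup$noiseIdx, testMask, crossTime, testCond)
    acc <- if (is.null(acc)) res$D else acc + res$D
    nT <- nT + res$nTest
  }
  list(D = acc / folds@nReps, nTest = nT / folds@nReps)
}

#' Time-resolved neural information within a session
#'
#' Repeated, condition-stratified k-fold cross-validated MANOVA: per fold
#' the noise precision and training coefficients come from the training
#' split (coefficients per time point; precision from the delay-window
#' mean), test coefficients and design cross-product from the test split;
#' D(t) is averaged over folds, then repetitions.
#'
#' @param epochs an [EpochArray-class] whose trial table has `condition_id`.
#' @param contrast a [Contrast-class].
#' @param folds a [FoldScheme-class].
#' @param noiseWindowMs window averaged for the precision estimate
#'   (default cue-1 offset to go-cue onset).
#' @return an [InformationResult-class] (vector over time).
#' @export
cvInformation <- function(epochs, contrast, folds = foldScheme(),
                          noiseWindowMs = c(taskTimeline()$cue1OffsetMs,
                                            taskTimeline()$goOnsetMs)) {
  s <- decodeSetup(epochs, contrast, contrast, noiseWindowMs)
  res <- runRepetitions(s, folds)
  new("InformationResult", values = as.numeric(res$D),
      trainTimesMs = s$tm, testTimesMs = s$tm, mode = "within",
      variable = contrast@variable, nTest = res$nTest,
      meta = list(folds = folds))
}

#' Temporal generalization (cross-time decoding)
#'
#' Trains the estimator at one time point and tests at another, for all
#' pairs; the diagonal equals [cvInformation()] up to numerical precision.
#'
#' @inheritParams cvInformation
#' @return an [InformationResult-class] (matrix `train times x test times`).
#' @export
crossTimeInformation <- function(epochs, contrast, folds = foldScheme(),
                                 noiseWindowMs = c(taskTimeline()$cue1OffsetMs,
                                                   taskTimeline()$goOnsetMs)) {
  s <- decodeSetup(epochs, contrast, contrast, noiseWindowMs)
  res <- runRepetitions(s, folds, crossTime = TRUE)
  new("InformationResult", values = res$D,
      trainTimesMs = s$tm, testTimesMs = s$tm, mode = "cross-time",
      variable = contrast@variable, nTest = res$nTest,
      meta = list(folds = folds))
}

#' Cross-variable decoding
#'
#' Trains on one variable's contrast and tests on the other's, probing the
#' overlap of the two representations.  With `symmetric = TRUE` the two
#' directions are averaged.
#'
#' @inheritParams cvInformation
#' @param contrastTrain,contrastTest [Contrast-class] objects on the same
#'   condition table.
#' @param symmetric average both train/test directions?
#' @return an [InformationResult-class].
#' @export
crossVariableInformation <- function(epochs, contrastTrain, contrastTest,
                                     folds = foldScheme(), symmetric = FALSE,
                                     noiseWindowMs = c(taskTimeline()$cue1OffsetMs,
                                                       taskTimeline()$goOnsetMs)) {
  s <- decodeSetup(epochs, contrastTrain, contrastTest, noiseWindowMs)
  res <- runRepetitions(s, folds)
  D <- res$D
  if (symmetric) {
    s2 <- decodeSetup(epochs, contrastTest, contrastTrain, noiseWindowMs)
    D <- (D + runRepetitions(s2, folds)$D) / 2
  }
  new("InformationResult", values = as.numeric(D),
      trainTimesMs = s$tm, testTimesMs = s$tm, mode = "cross-variable",
      variable = paste(contrastTrain@variable, contrastTest@variable,
                       sep = "->"),
      nTest = res$nTest, meta = list(folds = folds))
}

#' Split-condition decoding
#'
#' Trains the contrast on all conditions but tests only on one level of the
#' other variable (e.g. content information within vocalized trials): the
#' test contrast and the test trials are restricted to the split level.
#'
#' @inheritParams cvInformation
#' @param splitVariable `"production"` or `"vowel"`.
#' @param splitLevel level of `splitVariable` kept on the test side.
#' @return an [InformationResult-class].
#' @export
splitConditionInformation <- function(epochs, contrast, splitVariable,
                                      splitLevel, folds = foldScheme(),
                                      noiseWindowMs = c(taskTimeline()$cue1OffsetMs,
                                                        taskTimeline()$goOnsetMs)) {
  cte <- restrictContrast(contrast, splitVariable, splitLevel)
  s <- decodeSetup(epochs, contrast, cte, noiseWindowMs)
  splitConds <- which(rowSums(cte@weights != 0) > 0)
  col <- if (splitVariable == "production") "production" else "vowel"
  mask <- cte@conditions[[col]][s$cond] == splitLevel
  stopIfNot(any(mask), "empty split")
  res <- runRepetitions(s, folds, testMask = mask, testCond = splitConds)
  new("InformationResult", values = as.numeric(res$D),
      trainTimesMs = s$tm, testTimesMs = s$tm, mode = "split",
      variable = contrast@variable, nTest = res$nTest,
      meta = list(folds = folds, splitVariable = splitVariable,
                  splitLevel = splitLevel))
}

#' Cross-session decoding
#'
#' Twofold cross-validation in which the two recording sessions serve as
#' training and test sets alternately.  Because the glyph-to-meaning
#' assignments are counterbalanced and block-specific drifts are
#' independent across sessions, an additive glyph-locked cue pattern
#' contributes no positive information in expectation, making this the
#' cue-confound control analysis.
#'
#' @param epochsSession1,epochsSession2 [EpochArray-class] objects with
#'   matching channels and time axes.
#' @param contrast a [Contrast-class].
#' @param noiseWindowMs precision-estimation window (ms).
#' @return an [InformationResult-class].
#' @export
crossSessionInformation <- function(epochsSession1, epochsSession2, contrast,
                                    noiseWindowMs = c(taskTimeline()$cue1OffsetMs,
                                                      taskTimeline()$goOnsetMs)) {
  stopIfNot(nChannels(epochsSession1) == nChannels(epochsSession2) &&
              nSamples(epochsSession1) == nSamples(epochsSession2),
            "sessions must share channels and time axis")
  c1 <- sort(unique(trialTable(epochsSession1)$condition_id))
  c2 <- sort(unique(trialTable(epochsSession2)$condition_id))
  stopIfNot(identical(c1, c2), "sessions must share the condition set")
  n1 <- nTrials(epochsSession1)
  Y <- array(0, dim = c(n1 + nTrials(epochsSession2),
                        nChannels(epochsSession1),
                        nSamples(epochsSession1)))
  Y[seq_len(n1), , ] <- epochData(epochsSession1)
  Y[-seq_len(n1), , ] <- epochData(epochsSession2)
  ct <- contrast@conditions
  cond <- match(c(trialTable(epochsSession1)$condition_id,
                  trialTable(epochsSession2)$condition_id), ct$condition_id)
  stopIfNot(!anyNA(cond), "condition codes outside the contrast table")
  tm <- timesMs(epochsSession1)
  noiseIdx <- which(tm >= noiseWindowMs[1L] & tm <= noiseWindowMs[2L])
  folds <- list(list(train = seq_len(n1), test = seq_len(nrow(Y))[-seq_len(n1)]),
                list(train = seq_len(nrow(Y))[-seq_len(n1)],
                     test = seq_len(n1)))
  res <- cvEngine(Y, cond, nrow(ct), contrast@weights, contrast@weights,
                  folds, noiseIdx)
  new("InformationResult", values = as.numeric(res$D),
      trainTimesMs = tm, testTimesMs = tm, mode = "cross-session",
      variable = contrast@variable, nTest = res$nTest, meta = list())
}

#' Expected cross-information benchmark
#'
#' The value cross-decoding would reach if two representations were
#' identical up to magnitude: the signed geometric mean
#' `sign(D1) sign(D2) sqrt(|D1 D2|)`.  Observed cross-information below
#' this benchmark indicates non-identical representations.
#'
#' @param D1,D2 pattern distinctness in the two contexts (vectorized).
#' @return expected cross-information, same shape.
#' @examples
#' expectedCrossInformation(0.01, 0.04)   # 0.02
#' @export
expectedCrossInformation <- function(D1, D2) {
  sign(D1) * sign(D2) * sqrt(abs(D1 * D2))
}
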