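## Shared fixtures, built in code.  Expensive objects are cached so several
## test files can reuse one small simulated world.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures)
}

tinySpace <- function() fixture("space", function() makeSourceSpace(30, seed = 1))
tinyLeadfield <- function() fixture("lf", function()
  makeLeadfield(tinySpace(), 16, seed = 1))

## one participant's two simulated sessions at a small profile
tinySessions <- function() fixture("sessions", function() {
  sp <- tinySpace(); lf <- tinyLeadfield()
  eff <- effectSpec(sp, seed = 2)
  nz <- noiseSpec(seed = 3)
  lapply(1:2, function(ss) {
    des <- buildSessionDesign("P01", ss, seed = 42)
    simulateSession(des, eff, nz, lf, sp, seed = 100 + ss, fs = 40)
  })
})

tinyEpochs <- function() fixture("epochs", function()
  baselineCorrect(tinySessions()[[1L]]@epochs))

delay1Win <- c(350, 2100)
delay2Win <- c(2450, 4200)

## Condition-labelled pure-noise epochs: the zero-amplitude generator limit
## at reduced dimensions (labels independent of the data by construction).
nullEpochs <- function(nPerCond = 12, K = 4, p = 6, Tn = 6, seed = 1,
                       conditions = nullConditions(K)) {
  n <- nPerCond * K
  withr::with_seed(seed, {
    dat <- array(rnorm(n * p * Tn), dim = c(n, p, Tn))
  })
  trials <- data.frame(condition_id = rep(seq_len(K), each = nPerCond))
  epochArray(dat, samplingRate = 10, tstartMs = 0, trials = trials)
}

nullConditions <- function(K = 4) {
  data.frame(condition_id = seq_len(K),
             vowel = rep(c("u", "schwa"), length.out = K),
             production = rep(c("vocalized", "imagined"), each = K / 2))
}

nullContentContrast <- function(K = 4) {
  ct <- nullConditions(K)
  contrastFromWeights(ifelse(ct$vowel == "u", 1, -1), "content", ct)
}

nullProductionContrast <- function(K = 4) {
  ct <- nullConditions(K)
  contrastFromWeights(ifelse(ct$production == "vocalized", 1, -1),
                      "production", ct)
}

## Independent naive reference for cross-validated pattern distinctness.
## Deliberately written with explicit loops, colMeans and solve(); shares
## only the fold assignment (an input) with the package implementation.
referenceCvInformation <- function(Y, cond, contrast, foldList, noiseIdx) {
  K <- length(unique(cond))
  p <- dim(Y)[2L]; Tn <- dim(Y)[3L]
  cvec <- as.numeric(contrast)
  Dsum <- numeric(Tn)
  for (fold in foldList) {
    tr <- fold$train; te <- fold$test
    condMeans <- function(idx, tpt) {
      B <- matrix(0, K, p)
      for (k in seq_len(K)) {
        rows <- idx[cond[idx] == k]
        B[k, ] <- colMeans(Y[rows, , tpt, drop = FALSE][, , 1, drop = FALSE])
      }
      B
    }
    ## noise precision from window-mean residuals of the training set
    Ytw <- matrix(0, length(tr), p)
    for (ii in seq_along(tr))
      Ytw[ii, ] <- rowMeans(matrix(Y[tr[ii], , noiseIdx], p))
    Btw <- matrix(0, K, p)
    for (k in seq_len(K))
      Btw[k, ] <- colMeans(Ytw[cond[tr] == k, , drop = FALSE])
    Xi <- Ytw - Btw[cond[tr], ]
    fE <- length(tr) - K
    SigInv <- (fE - p - 1) * solve(t(Xi) %*% Xi)
    cntTe <- as.numeric(table(factor(cond[te], levels = seq_len(K))))
    XtX <- diag(cntTe)
    for (tpt in seq_len(Tn)) {
      Btr <- condMeans(tr, tpt)
      Bte <- condMeans(te, tpt)
      wtr <- as.numeric(t(cvec) %*% Btr) / sum(cvec^2)
      wte <- as.numeric(t(cvec) %*% Bte) / sum(cvec^2)
      mid <- as.numeric(t(cvec) %*% XtX %*% cvec)
      Dsum[tpt] <- Dsum[tpt] +
        mid * as.numeric(t(wtr) %*% SigInv %*% wte) / length(te)
    }
  }
  Dsum / length(foldList)
}
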