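test_that("condition-mean fitting matches the normal equations", {
  ## two conditions, one trial each: B rows are the trial rows
  X <- rbind(c(1, 0), c(0, 1))
  Y <- rbind(c(1, 1), c(3, 3))
  expect_equal(fitConditionMeans(X, Y), Y, ignore_attr = TRUE)
  ## duplicated trials leave the means unchanged
  expect_equal(fitConditionMeans(rbind(X, X), rbind(Y, Y)), Y,
               ignore_attr = TRUE)
  ## random design: agrees with an explicit normal-equation solve
  set.seed(10)
  Xr <- matrix(rnorm(60), 20, 3)
  Yr <- matrix(rnorm(80), 20, 4)
  expect_equal(fitConditionMeans(Xr, Yr),
               solve(t(Xr) %*% Xr) %*% t(Xr) %*% Yr,
               tolerance = 1e-10, ignore_attr = TRUE)
  ## empty condition is reported by name
  expect_error(fitConditionMeans(cbind(c(1, 1), 0), Y), "condition 2")
})

test_that("the noise precision estimator is correctly scaled", {
  ## degrees of freedom arithmetic
  X <- model.matrix(~ 0 + gl(16, 16))
  np <- estimateNoisePrecision(X, matrix(rnorm(256 * 10), 256))
  expect_equal(np@fE, 240)
  ## white noise at large n: precision approaches the identity
  set.seed(11)
  n <- 5000; p <- 10
  Xw <- model.matrix(~ 0 + gl(2, n / 2))
  npw <- estimateNoisePrecision(Xw, matrix(rnorm(n * p), n))
  expect_lt(max(abs(npw@precision - diag(p))), 0.1)
  ## guard: as many channels as residual dof
  expect_error(estimateNoisePrecision(model.matrix(~ 0 + gl(2, 6)),
                                      matrix(rnorm(12 * 10), 12)),
               "insufficient trials")
})

test_that("pattern distinctness matches a term-by-term trace oracle", {
  ## fixed small instance: 4 conditions, 3 channels
  set.seed(12)
  K <- 4; p <- 3
  Btr <- matrix(rnorm(K * p), K)
  Bte <- matrix(rnorm(K * p), K)
  Ctr <- c(1, 1, -1, -1)
  Cte <- c(1, -1, 1, -1)
  XtX <- diag(c(5, 6, 4, 5))
  S <- crossprod(matrix(rnorm(p * p), p)) + diag(p)
  n <- 20
  D <- patternDistinctness(Btr, Bte, Ctr, Cte, XtX, S, n)
  ## naive expansion, scalar loops only
  wtr <- drop(t(Ctr) %*% Btr) / sum(Ctr^2)
  wte <- drop(t(Cte) %*% Bte) / sum(Cte^2)
  mid <- drop(t(Ctr) %*% XtX %*% Ctr)
  oracle <- 0
  for (i in seq_len(p)) for (j in seq_len(p))
    oracle <- oracle + wtr[i] * S[i, j] * wte[j]
  oracle <- oracle * mid / n
  expect_equal(D, oracle, tolerance = 1e-12)
  ## linearity: zero training coefficients give exactly zero
  expect_identical(patternDistinctness(0 * Btr, Bte, Ctr, Cte, XtX, S, n), 0)
  ## orthogonal contrasts with orthogonal noiseless patterns: exactly zero
  Bo <- rbind(c(1, 0, 0), c(-1, 0, 0), c(1, 0, 0), c(-1, 0, 0))   # test axis e1
  Bt2 <- rbind(c(0, 2, 0), c(0, 2, 0), c(0, -2, 0), c(0, -2, 0))  # train axis e2
  expect_equal(patternDistinctness(Bt2, Bo, Ctr, Cte, diag(4), diag(3), 4),
               0, tolerance = 1e-15)
  ## identical train/test contrast reduces to the projector form
  P <- Ctr %*% solve(t(Ctr) %*% Ctr) %*% t(Ctr)
  projForm <- sum(diag(t(Btr) %*% P %*% XtX %*% P %*% Bte %*% S)) / n
  expect_equal(patternDistinctness(Btr, Bte, Ctr, Ctr, XtX, S, n), projForm,
               tolerance = 1e-12)
  expect_error(patternDistinctness(Btr, Bte[, 1:2], Ctr, Cte, XtX, S, n),
               "conformable")
})

test_that("expected cross-information follows the signed geometric mean", {
  expect_equal(expectedCrossInformation(0.04, 0.04), 0.04)
  expect_equal(expectedCrossInformation(0.01, 0.04), 0.02)
  expect_equal(expectedCrossInformation(-0.01, 0.04), -0.02)
})

test_that("cvInformation equals an independent from-scratch reference", {
  ep <- nullEpochs(nPerCond = 10, K = 4, p = 5, Tn = 4, seed = 21)
  d <- epochData(ep)
  ## plant a small content effect so the comparison is not around zero
  ct <- nullConditions(4)
  eff <- outer(ifelse(ct$vowel == "u", 1, -1)[trialTable(ep)$condition_id],
               seq_len(5) / 5)
  d <- d + array(rep(as.vector(eff), 4), dim = dim(d))
  ep <- epochArray(d, 10, 0, trials = trialTable(ep))
  con <- nullContentContrast()
  foldList <- vocalinfo:::stratifiedFolds(trialTable(ep)$condition_id, 5, 77)
  Dref <- referenceCvInformation(epochData(ep), trialTable(ep)$condition_id,
                                 con@weights, foldList, noiseIdx = 1:4)
  ## package result with the identical fold assignment, one repetition
  res <- vocalinfo:::cvEngine(epochData(ep), trialTable(ep)$condition_id, 4,
                              con@weights, con@weights, foldList,
                              noiseIdx = 1:4)
  expect_equal(as.numeric(res$D), Dref, tolerance = 1e-10)
  expect_gt(mean(Dref), 0)
})

test_that("the cross-time diagonal equals within-session information", {
  ep <- subsetEpochs(tinyEpochs(), samples = seq(1, 201, by = 10))
  con <- makeContrast("content", orders = "content_first")
  fs1 <- foldScheme(5, 1, seed = 3)
  w <- informationValues(cvInformation(ep, con, fs1))
  m <- informationValues(crossTimeInformation(ep, con, fs1))
  expect_equal(diag(m), w, tolerance = 1e-10)
  ## causality of the plant: information after the content cue, none before
  ## (full time axis, averaged repetitions, so the pre-cue mean is stable)
  wf <- informationValues(cvInformation(tinyEpochs(), con,
                                        foldScheme(5, 2, seed = 3)))
  tmf <- timesMs(tinyEpochs())
  expect_gt(mean(wf[tmf >= delay1Win[1] & tmf <= delay1Win[2]]),
            5 * abs(mean(wf[tmf < 0])))
})

test_that("D is invariant to invertible channel mixing", {
  ep <- subsetEpochs(tinyEpochs(), samples = seq(1, 201, by = 20))
  con <- makeContrast("content")
  fs1 <- foldScheme(5, 1, seed = 4)
  D0 <- informationValues(cvInformation(ep, con, fs1))
  set.seed(13)
  Q <- qr.Q(qr(matrix(rnorm(16 * 16), 16)))
  A <- Q %*% (runif(16, 0.5, 2) * t(Q))     # well-conditioned, invertible
  d <- epochData(ep)
  dm <- array(0, dim = dim(d))
  for (i in seq_len(dim(d)[1L])) dm[i, , ] <- t(A) %*% d[i, , ]
  epm <- epochArray(dm, samplingRate = samplingRate(ep),
                    tstartMs = timesMs(ep)[1L], trials = trialTable(ep))
  D1 <- informationValues(cvInformation(epm, con, fs1))
  expect_lt(max(abs(D1 - D0) / (abs(D0) + 1e-6)), 1e-8)
})

test_that("information grows with the planted amplitude", {
  sp <- tinySpace(); lf <- tinyLeadfield()
  des <- buildSessionDesign("P04", 1, seed = 21)
  nz <- noiseSpec(seed = 3)
  fs1 <- foldScheme(5, 1, seed = 5)
  con <- makeContrast("content")
  dOf <- function(a) {
    eff <- effectSpec(sp, seed = 2, aContent = a)
    sim <- simulateSession(des, eff, nz, lf, sp, seed = 6, fs = 10)
    v <- informationValues(cvInformation(baselineCorrect(sim@epochs), con, fs1))
    tm <- timesMs(sim@epochs)
    mean(v[tm >= delay1Win[1] & tm <= delay2Win[2]])
  }
  d1 <- dOf(0.5); d2 <- dOf(1); d3 <- dOf(2)
  expect_gt(d2, d1)
  expect_gt(d3, d2)
})

test_that("stratification and split guards raise informative errors", {
  ep <- nullEpochs(nPerCond = 4, K = 4, p = 3, Tn = 3, seed = 30)
  con <- nullContentContrast()
  expect_error(cvInformation(ep, con, foldScheme(5, 1, seed = 1)),
               "stratification")
  ## split level absent from the condition table errors out
  expect_error(splitConditionInformation(tinyEpochs(),
                                         makeContrast("content"),
                                         "production", "whispered",
                                         foldScheme(5, 1, seed = 1)),
               "split")
})

test_that("cross-session decoding requires aligned sessions", {
  eps <- lapply(tinySessions(), function(s) baselineCorrect(s@epochs))
  expect_error(crossSessionInformation(subsetEpochs(eps[[1]], channels = 1:8),
                                       eps[[2]], makeContrast("content")),
               "channels")
  ## and runs when aligned, with positive content information in delay 2
  sub <- lapply(eps, subsetEpochs, samples = seq(1, 201, by = 5))
  cs <- crossSessionInformation(sub[[1]], sub[[2]], makeContrast("content"))
  tm <- timesMs(sub[[1]])
  expect_gt(mean(informationValues(cs)[tm >= delay2Win[1] &
                                         tm <= delay2Win[2]]), 0)
})

test_that("cross-session decoding cancels a glyph-locked cue confound that
           inflates within-session information", {
  sp <- makeSourceSpace(12, seed = 1)
  lf <- makeLeadfield(sp, 8, seed = 1)
  nz <- noiseSpec(seed = 2, sourceNoiseSd = 0)
  cc <- makeContrast("content", orders = "content_first")
  one <- function(seed) {
    ## confound only: zero true effects, block-drifting glyph patterns
    eff <- effectSpec(sp, seed = seed, aContent = 0, aProd = 0, aLate = 0,
                      aEffort = 0, aCue = 3, cueDriftSd = 1)
    s1 <- simulateSession(buildSessionDesign("P", 1, seed = seed), eff, nz,
                          lf, sp, seed = seed * 2 + 1, fs = 8)
    s2 <- simulateSession(buildSessionDesign("P", 2, seed = seed), eff, nz,
                          lf, sp, seed = seed * 2 + 2, fs = 8)
    ep1 <- baselineCorrect(s1@epochs); ep2 <- baselineCorrect(s2@epochs)
    tm <- timesMs(ep1)
    cueT <- (tm >= 0 & tm <= 250) | (tm >= 2100 & tm <= 2350)
    w <- informationValues(cvInformation(ep1, cc, foldScheme(5, 1, seed = seed)))
    x <- informationValues(crossSessionInformation(ep1, ep2, cc))
    c(within = mean(w[cueT]), cross = mean(x[cueT]))
  }
  r <- t(vapply(1:200, one, c(within = 0, cross = 0)))
  ## the confound masquerades as information within a session ...
  expect_gt(mean(r[, "within"]), 10 * sd(r[, "within"]) / sqrt(nrow(r)))
  ## ... but cancels in expectation across sessions
  expect_lt(abs(mean(r[, "cross"])), 2 * sd(r[, "cross"]) / sqrt(nrow(r)))
})

test_that("the session-2 leadfield perturbation attenuates cross-session
           information without destroying it", {
  sp <- makeSourceSpace(12, seed = 1)
  lf <- makeLeadfield(sp, 8, seed = 1)
  one <- function(seed, gainSd, angle) {
    eff <- effectSpec(sp, seed = seed)
    nz <- noiseSpec(seed = 2, session2GainSd = gainSd,
                    session2AngleDeg = angle)
    s1 <- simulateSession(buildSessionDesign("P", 1, seed = seed), eff, nz,
                          lf, sp, seed = seed * 2 + 1, fs = 8)
    s2 <- simulateSession(buildSessionDesign("P", 2, seed = seed), eff, nz,
                          lf, sp, seed = seed * 2 + 2, fs = 8)
    ep1 <- baselineCorrect(s1@epochs); ep2 <- baselineCorrect(s2@epochs)
    tm <- timesMs(ep1); d2 <- tm >= 2450 & tm <= 4200
    mean(informationValues(crossSessionInformation(
      ep1, ep2, makeContrast("content")))[d2])
  }
  pert <- vapply(1:16, one, 0, gainSd = 0.3, angle = 15)
  clean <- vapply(1:16, one, 0, gainSd = 0, angle = 0)
  expect_lt(pairedT(clean, pert, "greater")$p_raw, 0.05)
  expect_gt(oneSampleT(pert, "greater")$t, 3)   # still well above zero
})
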