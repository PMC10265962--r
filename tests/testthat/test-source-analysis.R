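test_that("LCMV weights satisfy the unit-gain constraint", {
  sp <- tinySpace(); lf <- tinyLeadfield()
  set.seed(14)
  C <- crossprod(matrix(rnorm(16 * 40), 40, 16)) / 40
  filt <- lcmvWeights(lf, C, sp)
  for (s in c(1L, 10L, 30L)) {
    L <- t(lf@gain[s, , ])
    expect_equal(filt@weights[s, , ] %*% L, diag(3), tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
  ## identity covariance reduces to the pseudoinverse of the leadfield
  filtI <- lcmvWeights(lf, diag(16), sp, regularization = 0)
  s <- 5L
  L <- t(lf@gain[s, , ])
  expect_equal(filtI@weights[s, , ], solve(t(L) %*% L) %*% t(L),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("beamformer power localizes a single active source", {
  sp <- tinySpace(); lf <- tinyLeadfield()
  active <- 12L
  L <- vocalinfo:::collapseLeadfield(lf, sp)
  set.seed(15)
  src <- matrix(rnorm(200), 1)                      # 1 x time activity
  sens <- crossprod(L[active, , drop = FALSE], src) +
    matrix(rnorm(16 * 200, sd = 0.01), 16)
  C <- tcrossprod(sens) / 200
  filt <- lcmvWeights(lf, C, sp)
  ep <- epochArray(array(sens, c(1, 16, 200)), samplingRate = 100)
  sep <- projectToSources(ep, filt, combineOrientations = FALSE)
  pow <- colSums(matrix(rowSums(epochData(sep)[1, , ]^2), 3))
  hits <- order(pow, decreasing = TRUE)[1:3]
  expect_true(active %in% hits ||
                any(hits %in% sp@neighbors[[active]]))
})

test_that("source projection respects shapes and linearity", {
  sp <- tinySpace(); lf <- tinyLeadfield()
  filt <- lcmvWeights(lf, diag(16), sp)
  ep <- epochArray(array(0, c(2, 16, 10)), samplingRate = 100)
  sep <- projectToSources(ep, filt)
  expect_equal(nChannels(sep), 90L)                 # 30 sources x 3
  expect_true(all(epochData(sep) == 0))             # zero in, zero out
  comb <- projectToSources(ep, filt, combineOrientations = TRUE)
  expect_equal(nChannels(comb), 30L)
  expect_true("hemisphere" %in% names(channelInfo(comb)))
  expect_error(projectToSources(subsetEpochs(ep, channels = 1:4), filt),
               "channels")
})

test_that("searchlight maps localize a planted single-source effect", {
  ## the searchlight dimension (3 x (1 + neighbors)) must stay below the
  ## sensor rank, so this fixture uses a denser sensor array
  sp <- tinySpace()
  lf <- makeLeadfield(sp, 40, seed = 9)
  des <- buildSessionDesign("P05", 1, seed = 31)
  tr <- trialTable(des)
  active <- 7L
  L <- vocalinfo:::collapseLeadfield(lf, sp)
  set.seed(16)
  Tn <- 20
  sgn <- ifelse(tr$vowel == "u", 1, -1)
  sens <- array(rnorm(320 * 40 * Tn, sd = 0.5), c(320, 40, Tn))
  for (i in 1:320)
    sens[i, , ] <- sens[i, , ] + outer(L[active, ] * sgn[i] * 2, rep(1, Tn))
  ep <- epochArray(sens, samplingRate = 10, tstartMs = 0, trials = tr)
  filt <- lcmvWeights(lf, diag(40), sp)
  sep <- projectToSources(ep, filt)
  win <- data.frame(label = "all", startMs = 0, endMs = 2000)
  sl <- searchlightInformation(sep, sp, makeContrast("content"),
                               folds = foldScheme(4, 1, seed = 6),
                               windows = win, noiseWindowMs = c(0, 2000))
  expect_true(all(sl@ok))
  best <- which.max(sl@D[, 1])
  expect_true(best == active || best %in% sp@neighbors[[active]])
})

test_that("the lateralization index is the left-right mean difference", {
  win <- data.frame(label = c("w1", "w2"), startMs = 0, endMs = 1)
  hemi <- rep(c("left", "right"), each = 5)
  ## symmetric map: LI exactly zero
  D <- matrix(rep(seq_len(5), 4), 10, 2)
  sl <- new("SearchlightResult", D = D, windows = win, hemisphere = hemi,
            ok = rep(TRUE, 10), meta = list())
  expect_equal(unname(lateralizationIndex(sl)), c(0, 0))
  ## left = right + c gives LI = c
  D2 <- D; D2[1:5, ] <- D2[1:5, ] + 0.3
  sl2 <- new("SearchlightResult", D = D2, windows = win, hemisphere = hemi,
             ok = rep(TRUE, 10), meta = list())
  expect_equal(unname(lateralizationIndex(sl2)), c(0.3, 0.3))
  ## an empty hemisphere is an error
  sl3 <- new("SearchlightResult", D = D, windows = win,
             hemisphere = rep("left", 10), ok = rep(TRUE, 10), meta = list())
  expect_error(lateralizationIndex(sl3), "hemisphere")
})

test_that("source subsetting picks spread-out locations deterministically", {
  sp <- makeSourceSpace(100, seed = 2)
  idx <- selectSourceSubset(sp, 50)
  expect_length(idx, 50L)
  expect_identical(idx, selectSourceSubset(sp, 50))
})
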