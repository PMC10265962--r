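mkEpochs <- function(dat, fs = 300, t0 = -500) {
  if (length(dim(dat)) == 1L) dim(dat) <- c(1L, 1L, length(dat))
  epochArray(dat, samplingRate = fs, tstartMs = t0)
}

test_that("channel jumps are detected and corrected", {
  set.seed(1)
  n <- 600
  x <- sin(2 * pi * 3 * seq_len(n) / 300) + rnorm(n, sd = 0.05)
  s <- mad(diff(x))
  xj <- x
  xj[300:n] <- xj[300:n] + 50 * s
  ep <- repairChannelJumps(mkEpochs(array(xj, c(1, 1, n))))
  y <- as.numeric(epochData(ep))
  expect_lt(max(abs(diff(y))), 20 * s)
  expect_lt(max(abs(y - x)), 10 * s)
  ## two jumps on one channel are both corrected
  xj2 <- x
  xj2[200:n] <- xj2[200:n] + 60 * s
  xj2[400:n] <- xj2[400:n] - 45 * s
  y2 <- as.numeric(epochData(repairChannelJumps(mkEpochs(array(xj2, c(1, 1, n))))))
  expect_lt(max(abs(diff(y2))), 20 * s)
  ## jump-free input is untouched
  y3 <- as.numeric(epochData(repairChannelJumps(mkEpochs(array(x, c(1, 1, n))))))
  expect_identical(y3, x)
})

test_that("the zero-phase Butterworth filter has the specified response", {
  fs <- 300; n <- 3000
  t <- seq_len(n) / fs
  ## 1 Hz passband tone preserved within 1%
  ep <- mkEpochs(array(sin(2 * pi * 1 * t), c(1, 1, n)), fs = fs)
  y <- as.numeric(epochData(zeroPhaseLowpass(ep, 30)))
  mid <- 500:2500
  expect_equal(max(abs(y[mid])), 1, tolerance = 0.01)
  ## 100 Hz stopband tone attenuated by more than 40 dB
  ep2 <- mkEpochs(array(sin(2 * pi * 100 * t), c(1, 1, n)), fs = fs)
  y2 <- as.numeric(epochData(zeroPhaseLowpass(ep2, 30)))
  expect_lt(20 * log10(max(abs(y2[mid]))), -40)
  ## impulse response is symmetric (zero phase)
  imp <- numeric(n); imp[n / 2] <- 1
  yi <- as.numeric(epochData(zeroPhaseLowpass(mkEpochs(array(imp, c(1, 1, n)),
                                                       fs = fs), 30)))
  k <- 60
  expect_equal(yi[n / 2 + seq_len(k)], yi[n / 2 - seq_len(k)],
               tolerance = 1e-6)
  expect_error(zeroPhaseLowpass(ep, 200), "Nyquist")
})

test_that("resampling preserves duration, DC level and time-zero alignment", {
  fs <- 2342.75; n <- 7031
  set.seed(2)
  ep <- mkEpochs(array(rnorm(n), c(1, 1, n)), fs = fs, t0 = -500)
  out <- resampleTo(ep, 300)
  expect_equal(nSamples(out), 900, tolerance = 2)
  expect_true(any(abs(timesMs(out)) < 1e-9))   # grid anchored at 0
  ## identity when target equals current rate
  expect_identical(epochData(resampleTo(ep, fs)), epochData(ep))
  ## DC input stays DC
  dc <- mkEpochs(array(2.5, c(1, 1, 1000)), fs = 300)
  expect_equal(as.numeric(epochData(resampleTo(dc, 100))),
               rep(2.5, nSamples(resampleTo(dc, 100))), tolerance = 1e-9)
  expect_error(resampleTo(dc, 400), "upsampling")
})

test_that("baseline correction zeroes the pre-cue window", {
  set.seed(3)
  ep <- mkEpochs(array(rnorm(2 * 3 * 400, mean = 5), c(2, 3, 400)),
                 fs = 300, t0 = -500)
  out <- baselineCorrect(ep)
  tm <- timesMs(out)
  bl <- apply(epochData(out)[, , tm >= -500 & tm <= 0, drop = FALSE],
              c(1, 2), mean)
  expect_equal(max(abs(bl)), 0, tolerance = 1e-12)
  ## constant trial becomes all zero
  cst <- mkEpochs(array(7, c(1, 1, 400)), fs = 300, t0 = -500)
  expect_equal(max(abs(epochData(baselineCorrect(cst)))), 0)
  expect_error(baselineCorrect(ep, c(-5000, -4000)), "window")
})

test_that("the vocal-onset detector recovers planted onsets", {
  fs <- 2343.75
  ref <- simulateAudio("imagined", seed = 99)$wave
  windowSamples <- round(42.66 / 1000 * fs)
  expect_equal(windowSamples, 100L)
  errs <- vapply(1:25, function(i) {
    a <- simulateAudio("vocalized", seed = i)
    det <- detectVocalOnset(a$wave, ref, fs)
    expect_true(det$detected)
    det$latencyMs - a$onsetMs
  }, 0)
  expect_true(all(abs(errs) <= 42.66))      # within one median window
  expect_true(mean(abs(errs) <= 25) >= 0.99)
  ## silent (imagined) trial: nothing crosses the threshold
  sil <- detectVocalOnset(simulateAudio("imagined", seed = 5)$wave, ref, fs)
  expect_false(sil$detected)
  expect_error(detectVocalOnset(numeric(0), ref, fs), "empty")
})

test_that("trial selection applies the correctness and onset rules", {
  tab <- data.frame(
    production = c("imagined", "vocalized", "vocalized", "vocalized",
                   "imagined", "vocalized"),
    production_correct = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE),
    vowel_correct = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE),
    vocal_onset_ms = c(NA, 420, 500, -120, NA, 300),
    audio_missing = FALSE)
  expect_equal(selectValidTrials(tab),
               c(TRUE, TRUE, FALSE, FALSE, FALSE, TRUE))
  ## audio-missing session: vowel correctness alone qualifies
  tab$audio_missing <- TRUE
  expect_equal(selectValidTrials(tab),
               c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE))
  expect_error(selectValidTrials(tab[, 1:2]), "missing required columns")
})

test_that("farthest-point sensor subsetting spreads channels out", {
  big <- makeLeadfield(makeSourceSpace(20, seed = 1), 273, seed = 2)
  pos <- as.matrix(big@channels[, c("x", "y", "z")])
  idx <- selectSensorSubset(pos, 137)
  expect_length(idx, 137L)
  expect_equal(anyDuplicated(idx), 0L)
  expect_identical(selectSensorSubset(pos, nrow(pos)), seq_len(nrow(pos)))
  expect_error(selectSensorSubset(pos, 300), "exceed")
  ## maximin spread beats random subsets of the same size
  minDist <- function(ix) min(dist(pos[ix, ]))
  set.seed(4)
  rnd <- replicate(100, minDist(sample(nrow(pos), 137)))
  expect_gte(minDist(idx), median(rnd))
})

test_that("the composed pipeline runs in the canonical order and keeps
           trials aligned", {
  sim <- tinySessions()[[1L]]
  sub <- subsetEpochs(sim@epochs, trials = 1:40)
  out <- preprocess(sub, lp1Hz = 15, targetHz = 20, lp2Hz = 8)
  expect_equal(samplingRate(out), 20)
  expect_equal(nTrials(out), 40L)
  expect_identical(trialTable(out)$condition_id,
                   trialTable(sub)$condition_id)
  tm <- timesMs(out)
  bl <- apply(epochData(out)[, , tm >= -500 & tm <= 0, drop = FALSE],
              c(1, 2), mean)
  expect_equal(max(abs(bl)), 0, tolerance = 1e-10)
})
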