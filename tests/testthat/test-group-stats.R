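test_that("delay windows exclude the first 250 ms after each cue", {
  w <- delayWindows()
  expect_equal(w$startMs, c(350, 2450))
  expect_equal(w$endMs, c(2100, 4200))
})

test_that("delay averaging is the windowed mean", {
  tm <- seq(-500, 4500, by = 50)
  v <- rep(0.7, length(tm))
  expect_equal(unname(averageDelay(v, timesMsAxis = tm)), c(0.7, 0.7))
  ## a ramp averages to the window midpoint value
  expect_equal(unname(averageDelay(tm / 1000, timesMsAxis = tm)),
               c(mean(tm[tm >= 350 & tm <= 2100]),
                 mean(tm[tm >= 2450 & tm <= 4200])) / 1000)
  expect_error(averageDelay(v, data.frame(delay = 1, startMs = 9000,
                                          endMs = 9500), timesMsAxis = tm),
               "empty")
})

test_that("cross-time averaging excludes the diagonal band", {
  tm <- seq(0, 4400, by = 100)
  m <- matrix(1, length(tm), length(tm))
  ## constant matrix: mean is the constant whatever the exclusion
  expect_equal(averageCrossTimeWindow(m, c(350, 2100), c(350, 2100),
                                      trainTimesMs = tm, testTimesMs = tm), 1)
  ## the within-delay square loses the |dt| <= 100 ms band
  m2 <- m; diag(m2) <- 1e6
  for (k in 1) { m2[cbind(2:length(tm), 1:(length(tm) - 1))] <- 1e6
                 m2[cbind(1:(length(tm) - 1), 2:length(tm))] <- 1e6 }
  expect_equal(averageCrossTimeWindow(m2, c(350, 2100), c(350, 2100),
                                      trainTimesMs = tm, testTimesMs = tm), 1)
  ## disjoint delay-1 x delay-2 rectangle: nothing excluded
  set.seed(17)
  m3 <- matrix(rnorm(length(tm)^2), length(tm))
  ri <- tm >= 350 & tm <= 2100; ci <- tm >= 2450 & tm <= 4200
  expect_equal(averageCrossTimeWindow(m3, c(350, 2100), c(2450, 4200),
                                      trainTimesMs = tm, testTimesMs = tm),
               mean(m3[ri, ci]))
  expect_error(averageCrossTimeWindow(m, c(0, 50), c(0, 50),
                                      diagonalExclusionMs = 1000,
                                      trainTimesMs = tm, testTimesMs = tm),
               "excluded")
})

test_that("t tests match the closed-form oracle and guard degenerate input", {
  set.seed(18)
  v <- rnorm(24, mean = 0.5)
  out <- oneSampleT(v, "greater")
  tOracle <- mean(v) / (sd(v) / sqrt(24))
  expect_equal(out$t, tOracle, tolerance = 1e-12)
  expect_equal(out$p_raw, pt(tOracle, 23, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_error(oneSampleT(rep(1, 10), "greater"), "zero variance")
  ## paired test reduces to a one-sample test on differences
  a <- rnorm(12); b <- rnorm(12)
  expect_equal(pairedT(a, b, "two.sided")$t,
               oneSampleT(a - b, "two.sided")$t, tolerance = 1e-12)
  ## identical inputs: t = 0, two-tailed p = 1
  same <- pairedT(a, a, "two.sided")
  expect_equal(same$t, 0)
  expect_equal(same$p_raw, 1)
})

test_that("one-tailed t tests are calibrated under the null", {
  set.seed(19)
  rej <- mean(replicate(10000, {
    oneSampleT(rnorm(24), "greater")$p_raw < 0.05
  }))
  expect_gte(rej, 0.04)
  expect_lte(rej, 0.06)
})

test_that("BH correction matches the hand-computed step-up values", {
  expect_equal(fdrBH(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdrBH(0.03), 0.03)
  expect_equal(fdrBH(rep(1, 5)), rep(1, 5))
  ## a spread case, stepped through by hand:
  ## sorted p = .005 .02 .04 .10; m/i = 4 2 4/3 1
  ## adjusted = .02 .04 .0533... .10 (monotone from the top)
  expect_equal(fdrBH(c(0.04, 0.005, 0.10, 0.02)),
               c(0.04 * 4 / 3, 0.02, 0.10, 0.04))
  ## monotone in the raw p-values and clipped at 1
  p <- c(0.001, 0.2, 0.04, 0.8)
  adj <- fdrBH(p)
  expect_true(all(adj[order(p)] == cummax(adj[order(p)])))
  expect_true(all(adj >= p) && all(adj <= 1))
  expect_error(fdrBH(c(0.5, 1.2)), "0, 1")
})

test_that("Hanning smoothing preserves constants and has the stated FWHM", {
  fs <- 300
  x <- rep(2, 400)
  expect_equal(hanningSmooth(x, 100, fs), x, tolerance = 1e-10)
  expect_length(hanningSmooth(rnorm(400), 100, fs), 400L)
  ## impulse response: full width at half maximum = 100 ms +/- one sample
  imp <- numeric(401); imp[201] <- 1
  y <- hanningSmooth(imp, 100, fs)
  above <- which(y >= max(y) / 2)
  fwhmMs <- (max(above) - min(above) + 1) * 1000 / fs
  expect_lte(abs(fwhmMs - 100), 1000 / fs + 1e-9)
})
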