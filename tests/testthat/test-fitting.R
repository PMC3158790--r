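test_that("rebinning averages samples into 2% bins and flags empty bins", {
  tt <- seq(0, 99.9, by = 0.5)
  const <- data.frame(time = tt, delta = 5, sigma = 3, beta = 1)
  ptc <- rebinNormalize(const, bounds = c(0, 100))
  expect_equal(nrow(bandPower(ptc)), 50)
  expect_true(all(bandPower(ptc) == rep(c(5, 3, 1), each = 50)))
  # samples only in the first half: last 25 bins missing
  half <- const[const$time < 50, ]
  ptcH <- rebinNormalize(half, bounds = c(0, 100))
  expect_true(all(is.na(bandPower(ptcH)[26:50, ])))
  expect_true(all(!is.na(bandPower(ptcH)[1:25, ])))
  # linear ramp: bin means sit at bin centres (dense sampling)
  tt2 <- seq(0, 100, by = 0.01)
  ramp <- data.frame(time = tt2, delta = tt2, sigma = 1, beta = 1)
  ptcR <- rebinNormalize(ramp, bounds = c(0, 100))
  expect_equal(bandPower(ptcR)[, "delta"], binTimes(ptcR), tolerance = 1e-2)
  expect_error(rebinNormalize(const[0, ], bounds = c(0, 100)), "empty")
})

test_that("three-point smoothing averages neighbours and respects missing data", {
  expect_equal(smooth3(rep(4, 10)), rep(4, 10))
  expect_equal(smooth3(c(0, 3, 0, 3, 0)), c(1.5, 1, 2, 1, 1.5))
  # impulse spreads to a plateau of a third of its height
  x <- c(0, 0, 0, 9, 0, 0, 0)
  expect_equal(smooth3(x), c(0, 0, 3, 3, 3, 0, 0))
  # NA excluded from the local mean
  expect_equal(smooth3(c(1, NA, 3))[2], 2)
  expect_error(smooth3(c(1, 2)), "at least 3")
})

test_that("switchover detection finds alternating peaks and troughs", {
  # strictly increasing delta: single towards phase, no interior switchover
  plan <- detectSwitchovers(seq(1, 50))
  expect_identical(length(plan@switchTimes), 0L)
  expect_identical(taCount(plan), 1L)
  # single rise-then-fall: one switchover at the peak bin
  y <- c(seq(1, 25), seq(24, 1))
  plan2 <- detectSwitchovers(y)
  expect_identical(length(plan2@switchTimes), 1L)
  expect_equal(plan2@switchTimes, 50, tolerance = 2.1)  # peak bin centre
  # generate-then-detect round trip on a noiseless 3-cycle episode
  m <- threeCycleModel()
  d <- bandPower(predictPower(m))[, "delta"]
  rec <- detectSwitchovers(smooth3(d / max(d)))
  expect_identical(length(rec@switchTimes), 5L)
  expect_lt(max(abs(rec@switchTimes - m@plan@switchTimes)), 2.01)  # 1 bin
})

test_that("coefficient of determination follows its definition", {
  expect_equal(coefficientOfDetermination(1:5, 1:5), 100)
  expect_equal(coefficientOfDetermination(c(1, 2, 3), rep(2, 3)), 0)
  expect_equal(coefficientOfDetermination(c(1, 2, 3), c(1, 2, 4)), 50)
  expect_lt(coefficientOfDetermination(c(1, 2, 3), c(5, -2, 9)), 0)
  # missing pairs excluded
  expect_equal(coefficientOfDetermination(c(1, 2, NA, 3), c(1, 2, 9, 4)), 50)
  expect_error(coefficientOfDetermination(rep(1, 4), 1:4), "variance")
})

test_that("Fisher-z overall R^2 combines bands and has the right invariances", {
  expect_equal(round(overallR2(97.8, 82.0, 90.3), 1), 92.6)
  expect_equal(round(overallR2(88.6, 63.6, 84.7), 1), 81.2)
  # fixed point and symmetry
  for (x in c(10, 50, 95)) expect_equal(overallR2(x, x, x), x)
  expect_equal(overallR2(30, 60, 90), overallR2(90, 30, 60))
  # bounded by the extremes of the inputs
  expect_gt(overallR2(30, 60, 90), 30)
  expect_lt(overallR2(30, 60, 90), 90)
  expect_error(overallR2(100, 50, 50), "\\(0, 100\\)")
})

test_that("quality classes follow the published thresholds", {
  expect_identical(classifyFit(69.9), "VG")
  expect_identical(classifyFit(60.0), "VG")
  expect_identical(classifyFit(40.0), "G")
  expect_identical(classifyFit(59.9), "G")
  expect_identical(classifyFit(19.0), "F")
  expect_identical(classifyFit(18.9), "BF")
})

test_that("fitting a noiseless self-generated episode recovers the model", {
  m <- twoCycleModel()
  fit <- fitEpisode(predictPower(m))
  expect_true(all(abs(fit@model@bandScales / m@bandScales - 1) < 0.01))
  expect_lt(max(abs(fit@model@plan@switchTimes - m@plan@switchTimes)), 2.01)
  expect_true(all(fit@r2Band > 99.9))
  expect_identical(fit@taCount, 2L)
  expect_true(fit@converged)
  # residuals vanish to optimiser tolerance
  expect_lt(max(abs(fit@residuals), na.rm = TRUE), 0.1)
})

test_that("missing bins are excluded from fitting and do not bias the result", {
  m <- twoCycleModel()
  clean <- predictPower(m)
  pw <- bandPower(clean)
  pw[c(5, 20, 41), "delta"] <- NA
  pw[c(10, 30), "sigma"] <- NA
  holey <- powerTimeCourse(binTimes(clean), pw[, "delta"], pw[, "sigma"],
                           pw[, "beta"])
  fit <- fitEpisode(holey)
  expect_true(all(abs(fit@model@bandScales / m@bandScales - 1) < 0.01))
  expect_true(all(is.na(fit@residuals[c(5, 20, 41), "delta"])))
})

test_that("switchover recovery tolerates 10% multiplicative noise", {
  m <- twoCycleModel()
  ok <- vapply(1:40, function(i) {
    ptc <- generateEpisodeData(m, noiseModel(0.1, 0), seed = 5000 + i)
    sw <- fitEpisode(ptc)@model@plan@switchTimes
    length(sw) == 2 && max(abs(sw - c(40, 70))) <= 4  # within 2 bins
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})

test_that("freeing the probability vector recovers it without a significant R^2 gain", {
  m <- twoCycleModel()
  ptc <- generateEpisodeData(m, noiseModel(0.05, 0), seed = 11)
  fixed <- fitEpisode(ptc)
  free <- fitEpisode(ptc, fitConfig(freeProbabilities = TRUE, maxIter = 60))
  truth <- probVector(transitionProbabilities())
  expect_true(all(abs(probVector(free@model@probabilities) / truth - 1) < 0.3))
  expect_lt(free@r2Overall - fixed@r2Overall, 2)
})

test_that("the residual runs test behaves like a diagnostic should", {
  m <- twoCycleModel()
  fit <- fitEpisode(generateEpisodeData(m, noiseModel(0.1, 0), seed = 4))
  rt <- residualRunsTest(fit, "delta")
  expect_true(rt$runs >= 1)
  expect_true(is.finite(rt$p.value) && rt$p.value >= 0 && rt$p.value <= 1)
})
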