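test_that("closed-form phase occupancy matches the independent ODE oracle", {
  # frozen values computed with fixed-step RK4 integration of the chain
  expect_equal(as.numeric(phaseOccupancy(c(1, 0, 0), 0.13, 0.131, 10)),
               c(0.27253, 0.35256, 0.37494), tolerance = 1e-4)
  expect_equal(as.numeric(phaseOccupancy(c(1, 0, 0), 0.2, 0.6, 5)),
               c(0.36788, 0.15905, 0.47307), tolerance = 1e-4)
  # random parameter draws, general initial occupancy
  set.seed(42)
  for (i in 1:10) {
    occ0 <- stats::runif(3)
    p <- sort(stats::runif(2, 0.05, 0.8))
    tEnd <- stats::runif(1, 1, 15)
    ours <- as.numeric(phaseOccupancy(occ0, p[1], p[2], tEnd))
    oracle <- odeCascade(occ0, p[1], p[2], tEnd)
    expect_equal(ours, oracle, tolerance = 1e-6)
  }
})

test_that("phase occupancy is the identity at t = 0 and conserves the population", {
  expect_equal(as.numeric(phaseOccupancy(c(1, 0, 0), 0.3, 0.5, 0)),
               c(1, 0, 0))
  set.seed(7)
  for (i in 1:10) {
    occ0 <- stats::runif(3, 0, 2)
    m <- phaseOccupancy(occ0, stats::runif(1, 0.05, 0.9),
                        stats::runif(1, 0.05, 0.9), seq(0, 20, by = 0.5))
    expect_lt(max(abs(rowSums(m) - sum(occ0))), 1e-9)
    expect_true(all(m >= 0))
  }
})

test_that("near-equal rates converge to the analytic equal-rate limit", {
  p <- 0.13
  limit <- function(t) (0 + 1 * p * t) * exp(-p * t)
  for (eps in c(1e-6, 1e-10, 0)) {
    m <- phaseOccupancy(c(1, 0, 0), p, p + eps, c(2, 7, 12))
    expect_equal(as.numeric(m[, "middle"]), limit(c(2, 7, 12)),
                 tolerance = 1e-5)
  }
  expect_error(phaseOccupancy(c(1, 0, 0), -0.1, 0.2, 1), "positive")
  expect_error(phaseOccupancy(c(1, 0, 0), 0.1, 0.2, -1), "non-negative")
})

test_that("from a pure first-mode start the cascade has the canonical shape", {
  tt <- seq(0, 40, by = 0.1)
  m <- phaseOccupancy(c(1, 0, 0), 0.13, 0.131, tt)
  expect_true(all(diff(m[, "first"]) < 0))   # exponential decline
  expect_true(all(diff(m[, "last"]) > 0))    # S-curve rise
  mid <- m[, "middle"]
  pk <- which.max(mid)
  expect_true(all(diff(mid[1:pk]) > 0) && all(diff(mid[pk:length(mid)]) < 0))
  # the middle-mode peak occurs while the last mode is still rising
  tpk <- sigmaPeakTime(c(1, 0, 0), 0.13, 0.131)
  eps <- 1e-4
  lastSlope <- (phaseOccupancy(c(1, 0, 0), 0.13, 0.131, tpk + eps)[, "last"] -
                phaseOccupancy(c(1, 0, 0), 0.13, 0.131, tpk - eps)[, "last"]) / (2 * eps)
  expect_gt(lastSlope, 0)
})

test_that("sigma peak time matches the closed form and the grid-search oracle", {
  expect_equal(sigmaPeakTime(c(1, 0, 0), 0.2, 0.6), log(3) / 0.4,
               tolerance = 1e-9)
  # frozen brute-force grid maximisation values
  expect_equal(sigmaPeakTime(c(1, 0, 0), 0.13, 0.131), 7.66287,
               tolerance = 1e-4)
  # no source term: middle mode declines monotonically from the start
  expect_true(is.na(sigmaPeakTime(c(0, 0.8, 0), 0.3, 0.5)))
  # general initial occupancy: locate by brute force and compare
  occ0 <- c(0.6, 0.3, 0.1)
  tg <- seq(0, 30, by = 1e-4)
  mid <- phaseOccupancy(occ0, 0.25, 0.4, tg)[, "middle"]
  expect_equal(sigmaPeakTime(occ0, 0.25, 0.4), tg[which.max(mid)],
               tolerance = 1e-3)
})

test_that("simulated episodes are continuous at switchovers and cycle correctly", {
  m <- threeCycleModel()
  sw <- m@plan@switchTimes
  for (s in sw) {
    left <- simulateEpisode(m, grid = s - 1e-7)
    right <- simulateEpisode(m, grid = s + 1e-7)
    expect_equal(occupancyFrame(left)[, -1], occupancyFrame(right)[, -1],
                 tolerance = 1e-5)
  }
  # 3 towards-away cycles produce exactly 3 local maxima in delta
  traj <- simulateEpisode(m, grid = seq(0, 100, by = 0.25))
  d <- traj@delta
  nmax <- sum(diff(sign(diff(d))) < 0)
  expect_identical(nmax, 3L)
  # conservation along the full trajectory
  expect_lt(max(abs(traj@beta + traj@sigma + traj@delta - 1)), 1e-9)
  expect_error(simulateEpisode(m, grid = c(-5, 50)), "within")
})

test_that("occupancy maps to band power with scales and beta bias", {
  m <- twoCycleModel()
  traj <- simulateEpisode(m)
  p1 <- occupancyToPower(traj, c(delta = 1, sigma = 1, beta = 1), 0)
  expect_equal(bandPower(p1)[, "delta"], traj@delta)
  expect_equal(bandPower(p1)[, "beta"], traj@beta)
  pb <- occupancyToPower(modeOccupancy(0, 0.5, 0.5), c(delta = 1, sigma = 1, beta = 1), 2)
  expect_equal(bandPower(pb)[1, "beta"], c(beta = 2))
  # round trip: subtracting the bias restores the unbiased curve
  p2 <- occupancyToPower(traj, m@bandScales, m@betaBias)
  unbiased <- bandPower(p2)[, "beta"] - m@betaBias
  expect_equal(unbiased, m@bandScales[["beta"]] * traj@beta, tolerance = 1e-12)
})

test_that("Monte Carlo phase conserves counts, is seeded, and matches the closed form", {
  mc0 <- monteCarloPhase(c(500, 0, 0), 0, 0.3, dt = 0.05, tEnd = 5, seed = 1)
  expect_true(all(mc0$first == 500))
  mc <- monteCarloPhase(c(10000, 0, 0), 0.2, 0.6, dt = 0.01, tEnd = 5, seed = 3)
  expect_true(all(mc$first + mc$middle + mc$last == 10000))
  mc2 <- monteCarloPhase(c(10000, 0, 0), 0.2, 0.6, dt = 0.01, tEnd = 5, seed = 3)
  expect_identical(mc, mc2)
  # final first-mode fraction within 4 binomial standard errors of e^-1
  pTrue <- exp(-1)
  se <- sqrt(pTrue * (1 - pTrue) / 10000)
  expect_lt(abs(utils::tail(mc$first, 1) / 10000 - pTrue), 4 * se)
  expect_error(monteCarloPhase(c(10, 0, 0), 0.5, 0.5, dt = 3, tEnd = 5, seed = 1),
               "dt")
})

test_that("Monte Carlo replicate means converge to the closed form", {
  closed <- phaseOccupancy(c(200, 0, 0), 0.2, 0.6, 5)
  endState <- function(nrep) {
    ends <- vapply(seq_len(nrep), function(i) {
      mc <- monteCarloPhase(c(200, 0, 0), 0.2, 0.6, dt = 0.02, tEnd = 5,
                            seed = 100 + i)
      as.numeric(utils::tail(mc, 1)[, c("first", "middle", "last")])
    }, numeric(3))
    rowMeans(ends)
  }
  m200 <- endState(200)
  # mean of 200 replicates of 200 neurons: SE of each fraction < 0.25/sqrt(4e4)
  expect_lt(max(abs(m200 - as.numeric(closed))) / 200, 4 * 0.5 / sqrt(4e4))
})

test_that("trajectory export writes readable delimited text", {
  m <- twoCycleModel()
  f <- withr::local_tempfile(fileext = ".tsv")
  writeTrajectory(simulateEpisode(m), f)
  df <- read.delim(f)
  expect_named(df, c("time_pct", "n_beta", "n_sigma", "n_delta"))
  expect_equal(nrow(df), 50)
})
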