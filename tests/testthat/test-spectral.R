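test_that("band power isolates an on-grid tone and obeys Parseval", {
  fs <- 256
  tt <- seq(0, 8 - 1 / fs, by = 1 / fs)
  tone <- eegRecord(sin(2 * pi * 2 * tt), rate = fs)   # 2 Hz, inside delta
  bp <- epochBandPower(tone)
  expect_true(all(bp$delta > 0.4))
  expect_true(all(bp$sigma < 1e-6) && all(bp$beta < 1e-6))
  # zero signal: zero power everywhere
  z <- epochBandPower(eegRecord(rep(0, fs * 4), rate = fs))
  expect_true(all(as.matrix(z[, c("delta", "sigma", "beta")]) == 0))
  # white noise: summed spectrum matches time-domain variance within 1%
  set.seed(1)
  x <- rnorm(fs * 40)
  rec <- eegRecord(x, rate = fs)
  full <- epochBandPower(rec, bands = list(delta = c(0.25, fs / 2),
                                           sigma = c(12, 15),
                                           beta = c(18, 25)))
  expect_equal(mean(full$delta), stats::var(x), tolerance = 0.01)
  expect_error(epochBandPower(eegRecord(rnorm(200), rate = 40)), "Nyquist")
})

test_that("the RMS artefact filter flags bursts and poisons overlapping epochs", {
  fs <- 128
  set.seed(2)
  x <- rnorm(fs * 400)
  clean <- eegRecord(x, rate = fs)
  expect_true(all(artefactMask(clean)))
  # a 1-s burst of 10x amplitude is flagged, and only that second
  xb <- x
  xb[200 * fs + seq_len(fs)] <- 10 * xb[200 * fs + seq_len(fs)]
  burst <- eegRecord(xb, rate = fs)
  flags <- artefactMask(burst)
  expect_false(flags[201])
  expect_equal(sum(!flags), 1)
  # masked second removes the 4-s epochs containing it
  bpClean <- epochBandPower(clean, valid = artefactMask(clean))
  bpMasked <- epochBandPower(burst, valid = flags)
  expect_gt(sum(!is.na(bpMasked$delta)), 0)
  expect_equal(sum(is.na(bpMasked$delta)) - sum(is.na(bpClean$delta)), 1)
})

test_that("the 15-minute combining rule delimits REM and NREM episodes", {
  mkHyp <- function(gapEpochs) {
    hypnogram(c("W", "W", "S2", rep("S3", 30), rep("REM", 6),
                rep("S2", gapEpochs), rep("REM", 6), rep("S2", 30), "W"))
  }
  # 10 min of NREM between REM bouts: combined into one REM episode
  expect_warning(seg10 <- segmentEpisodes(mkHyp(30)), "NREM episode")
  expect_equal(nrow(seg10), 2)           # NREM before and after the REM episode
  expect_equal(seg10$startEpoch[1], 3)   # sleep onset at first S2
  expect_equal(seg10$endEpoch[1], 33)    # up to the epoch before REM
  expect_equal(seg10$startEpoch[2], 33 + 6 + 30 + 6 + 1)
  # 20 min between REM bouts: two REM episodes, an NREM episode between
  seg20 <- suppressWarnings(segmentEpisodes(mkHyp(60)))
  expect_equal(nrow(seg20), 3)
  expect_equal(seg20$startEpoch[2], 40)  # right after the first REM bout
  expect_equal(seg20$endEpoch[2], 99)    # up to the second REM bout
})

test_that("a single REM epoch starts a REM episode and trailing wake is ignored", {
  hyp <- hypnogram(c("S2", rep("S3", 45), "REM", rep("S2", 50)))
  seg <- suppressWarnings(segmentEpisodes(hyp))
  expect_equal(nrow(seg), 2)
  expect_equal(seg$endEpoch[1], 46)
  expect_equal(seg$startEpoch[2], 48)
  # appending wake after the final episode changes nothing
  hypW <- hypnogram(c(hyp@stages, rep("W", 40)))
  expect_identical(suppressWarnings(segmentEpisodes(hypW)), seg)
})

test_that("sleep latency and efficiency follow their definitions", {
  # lights off at epoch 1, first stage 2 at epoch 50: 49 epochs = 16.33 min
  st <- c(rep("W", 49), rep("S2", 60))
  expect_equal(sleepStatistics(hypnogram(st))$latencyMin, 49 / 3,
               tolerance = 1e-9)
  expect_equal(sleepStatistics(hypnogram(st))$efficiency, 1.0)
  # a 9-h sleep period with ~10.8 min of wake: efficiency 0.98
  span <- c(rep("S2", 800), rep("W", 32), rep("S3", 788))
  stats2 <- sleepStatistics(hypnogram(c("W", span)))
  expect_equal(round(stats2$efficiency, 2), 0.98)
  expect_error(sleepStatistics(hypnogram(c("W", "S1", "REM"))), "stage-2")
})

test_that("synthetic EEG runs through the spectral pipeline and refits", {
  m <- twoCycleModel()
  ee <- generateSyntheticEeg(m, fs = 128, episodeMin = 30, seed = 2)
  # band powers recovered from the EEG correlate with the generating curves
  pcs <- suppressWarnings(episodePowerCourses(ee$record, ee$hypnogram))
  expect_equal(length(pcs), 1)
  truthPw <- bandPower(predictPower(m))
  gotPw <- bandPower(pcs[[1]])
  for (b in c("delta", "sigma", "beta"))
    expect_gt(stats::cor(truthPw[, b], gotPw[, b], use = "complete.obs"), 0.9)
  fit <- fitEpisode(pcs[[1]])
  sw <- fit@model@plan@switchTimes
  expect_equal(length(sw), 2)
  expect_lt(max(abs(sw - c(40, 70))), 4.01)  # within 2 bins
})
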