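# Shared builders for test fixtures, all generated in code.

twoCycleModel <- function(scales = c(delta = 150, sigma = 30, beta = 10),
                          bias = 2) {
  episodeModel(plan = phasePlan(c(40, 70)), bandScales = scales,
               betaBias = bias)
}

threeCycleModel <- function() {
  episodeModel(plan = phasePlan(c(20, 35, 55, 68, 85)),
               bandScales = c(delta = 150, sigma = 30, beta = 10))
}

# A synthetic full night: four NREM episodes with REM tails, glued into one
# EEG record with a matching hypnogram.
fullNight <- function(seed = 1, fs = 128, episodeMin = 16) {
  plans <- list(phasePlan(c(40, 70)), phasePlan(c(30, 55, 80)),
                phasePlan(c(45, 75)), phasePlan(c(25, 50, 75)))
  samples <- numeric(0); stages <- character(0)
  for (i in 1:4) {
    m <- episodeModel(plan = plans[[i]],
                      bandScales = c(delta = 150 - 25 * i, sigma = 30,
                                     beta = 10))
    ee <- generateSyntheticEeg(m, fs = fs, episodeMin = episodeMin,
                               wakeMin = if (i == 1) 1 else 0, remMin = 3,
                               seed = seed + i)
    samples <- c(samples, ee$record@samples)
    stages <- c(stages, ee$hypnogram@stages)
  }
  list(record = eegRecord(samples, rate = fs, label = "synthetic-night"),
       hypnogram = hypnogram(stages))
}

# Fixed-step RK4 integration of the serial chain first -> middle -> last:
# the independent oracle for the closed-form phase solution.
odeCascade <- function(occ0, p1, p2, tEnd, dt = 1e-3) {
  deriv <- function(y) c(-p1 * y[1], p1 * y[1] - p2 * y[2], p2 * y[2])
  y <- occ0
  nstep <- max(1L, ceiling(tEnd / dt))
  dt <- tEnd / nstep   # land exactly on tEnd
  for (i in seq_len(nstep)) {
    k1 <- deriv(y); k2 <- deriv(y + dt / 2 * k1)
    k3 <- deriv(y + dt / 2 * k2); k4 <- deriv(y + dt * k3)
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  y
}
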