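# Seeded generators for every input the pipeline consumes: noisy band-power
# time courses, whole cohorts with known ground truth, paired SCN/SWA traces
# with a known switching schedule, and synthetic raw EEG with a hypnogram.

#' Noise model for synthetic band-power data
#'
#' Power is positive with roughly scale-proportional variability, so the
#' noise is multiplicative lognormal (unit median); bins are additionally
#' dropped at random to emulate artefact-masked data. The published analyses
#' state no noise model — this one is the package's documented stand-in.
#'
#' @param sigma Lognormal sigma of the multiplicative noise (>= 0,
#'   default 0.1, i.e. about 10\% coefficient of variation).
#' @param missing Probability that a bin is missing (in [0, 1), default 0).
#' @return A list of class \code{"NoiseModel"}.
#' @export
noiseModel <- function(sigma = 0.1, missing = 0) {
  stopifnot(sigma >= 0, missing >= 0, missing < 1)
  structure(list(sigma = sigma, missing = missing), class = "NoiseModel")
}

#' Generate a noisy band-power time course from an episode model
#'
#' Simulates the model on the 50-bin grid, maps occupancy to power with the
#' model's scales and beta bias, multiplies each bin by lognormal noise and
#' masks bins at random, all driven by the seed.
#'
#' @param model An \linkS4class{EpisodeModel}.
#' @param noise A [noiseModel()].
#' @param seed Integer seed.
#' @return A \linkS4class{PowerTimeCourse}.
#' @examples
#' m <- episodeModel(plan = phasePlan(c(40, 70)),
#'                   bandScales = c(delta = 150, sigma = 30, beta = 10))
#' ptc <- generateEpisodeData(m, noiseModel(0.1, 0.05), seed = 1)
#' @export
generateEpisodeData <- function(model, noise = noiseModel(), seed = 1L) {
  stopifnot(is(model, "EpisodeModel"), inherits(noise, "NoiseModel"))
  clean <- predictPower(model)
  pw <- bandPower(clean)
  withSeed(seed, {
    if (noise$sigma > 0)
      pw <- pw * matrix(stats::rlnorm(length(pw), 0, noise$sigma),
                        nrow(pw), ncol(pw))
    if (noise$missing > 0) {
      drop <- matrix(stats::runif(length(pw)) < noise$missing,
                     nrow(pw), ncol(pw))
      pw[drop] <- NA_real_
    }
  })
  powerTimeCourse(time = binTimes(clean), delta = pw[, "delta"],
                  sigma = pw[, "sigma"], beta = pw[, "beta"],
                  binWidth = clean@binWidth)
}

#' Random phase plan with a given number of towards-away cycles
#'
#' Draws 2*ta - 1 interior switchover times by stick-breaking over [0, 100]
#' (Dirichlet phase lengths) with a minimum phase length of
#' \code{min(8, 40/ta)}\% so that phases stay resolvable on the 2\% bin grid
#' even at high cycle counts.
#'
#' @param ta Number of towards-away cycles (>= 1).
#' @param seed Integer seed.
#' @return A \linkS4class{PhasePlan} starting with a towards phase and
#'   containing \code{ta} towards phases.
#' @export
randomPhasePlan <- function(ta, seed = 1L) {
  stopifnot(ta >= 1)
  nPhase <- 2L * as.integer(ta)      # ends with an away phase
  minLen <- min(8, 40 / ta)
  withSeed(seed, {
    g <- stats::rgamma(nPhase, shape = 2)
    lens <- minLen + (100 - nPhase * minLen) * g / sum(g)
  })
  phasePlan(cumsum(lens)[-nPhase])
}

#' Cohort specification for the synthetic generator
#'
#' Defaults emulate the reference cohort's study conditions: 30 subjects,
#' four NREM episodes whose mean TA counts rise across the night near
#' (5.2, 6.7, 6.8, 7.1) via shifted-binomial draws (dispersion matched to
#' the modest spread of observed TA counts, all counts >= 1), the common
#' probability vector, and 10\% multiplicative noise.
#'
#' @param nSubjects Number of subjects (default 30).
#' @param taMeans Target mean TA count per episode.
#' @param durations Episode durations in minutes.
#' @param probabilities A \linkS4class{TransitionProbabilities}.
#' @param bandScales Mean band scales (delta, sigma, beta) in uV^2.
#' @param betaBias Background beta power, uV^2.
#' @param noise A [noiseModel()].
#' @return A list of class \code{"CohortSpec"}.
#' @export
cohortSpec <- function(nSubjects = 30L,
                       taMeans = c(5.2, 6.7, 6.8, 7.1),
                       durations = c(70, 85, 90, 95),
                       probabilities = transitionProbabilities(),
                       bandScales = c(delta = 150, sigma = 30, beta = 10),
                       betaBias = 2,
                       noise = noiseModel(sigma = 0.1, missing = 0.02)) {
  stopifnot(all(taMeans >= 1), all(durations > 0))
  structure(list(nSubjects = as.integer(nSubjects), taMeans = taMeans,
                 durations = durations, probabilities = probabilities,
                 bandScales = bandScales, betaBias = betaBias, noise = noise),
            class = "CohortSpec")
}

#' Generate a synthetic cohort with known ground truth
#'
#' For every subject and episode: a TA count is drawn (1 + Poisson with mean
#' \code{taMeans - 1}), a random phase plan with that count, per-subject
#' lognormal variation of the band scales, and a noisy
#' \linkS4class{PowerTimeCourse} via [generateEpisodeData()]. The returned
#' truth table carries the generating plan and scales for recovery tests;
#' cohort TA means rise across episodes in expectation.
#'
#' @param spec A [cohortSpec()].
#' @param seed Integer seed.
#' @return A list with \code{data} (nested list: subject -> episode ->
#'   \linkS4class{PowerTimeCourse}), \code{truth} (data.frame subject, nrem,
#'   ta, duration) and \code{models} (nested list of generating
#'   \linkS4class{EpisodeModel}s).
#' @export
generateCohort <- function(spec = cohortSpec(), seed = 1L) {
  stopifnot(inherits(spec, "CohortSpec"))
  nEp <- length(spec$taMeans)
  data <- vector("list", spec$nSubjects)
  models <- vector("list", spec$nSubjects)
  truth <- NULL
  for (s in seq_len(spec$nSubjects)) {
    data[[s]] <- vector("list", nEp)
    models[[s]] <- vector("list", nEp)
    for (e in seq_len(nEp)) {
      sd1 <- childSeed(seed, (s - 1L) * nEp + e)
      # shifted binomial: mean taMeans[e], variance matched to the modest
      # between-subject spread of observed TA counts (well under Poisson)
      ta <- withSeed(sd1,
                     1L + stats::rbinom(1L, 8L, (spec$taMeans[e] - 1) / 8))
      plan <- randomPhasePlan(ta, seed = childSeed(sd1, 1L))
      scales <- withSeed(childSeed(sd1, 2L),
                         spec$bandScales * stats::rlnorm(3, 0, 0.2))
      names(scales) <- names(spec$bandScales)
      mdl <- episodeModel(probabilities = spec$probabilities, plan = plan,
                          bandScales = scales, betaBias = spec$betaBias)
      models[[s]][[e]] <- mdl
      data[[s]][[e]] <- generateEpisodeData(mdl, spec$noise,
                                            seed = childSeed(sd1, 3L))
      truth <- rbind(truth, data.frame(subject = s, nrem = e, ta = ta,
                                       duration = spec$durations[e]))
    }
  }
  list(data = data, truth = truth, models = models)
}

#' Generate paired SCN-activity and SWA traces with a known flip-flop schedule
#'
#' The SCN trace is a slowly varying baseline plus a two-level component that
#' switches at the schedule times (high during away phases — the wake/REM
#' zone — and low during towards phases) plus Gaussian noise. The SWA trace
#' is the anti-correlated response: it relaxes upward while the SCN is below
#' threshold and decays toward zero while above. Both are built at 10-s
#' resolution and binned at 60 s, mirroring minute-resolution activity data.
#'
#' @param switchTimes Increasing switch times in seconds within the record.
#' @param durationSec Total record length in seconds.
#' @param coupling Relaxation rate of the SWA response per second (default
#'   0.003, a time constant of about 5.5 min so the build-up and decline
#'   span a typical phase rather than saturating early).
#' @param noiseSd Gaussian noise SD on both traces, in percent-of-mean units
#'   (default 5). Alignment recovery degrades above about a third of the
#'   switching amplitude (documented bound: \code{noiseSd <= 15} with the
#'   default amplitude 50).
#' @param amplitude Half-separation of the two SCN levels (default 50).
#' @param seed Integer seed.
#' @return A list with \code{scn}, \code{swa} (both
#'   \linkS4class{ActivityTrace}), \code{threshold} (the true SCN threshold)
#'   and \code{schedule} (the switch times).
#' @export
generateScnSwa <- function(switchTimes, durationSec = 7200, coupling = 0.003,
                           noiseSd = 5, amplitude = 50, seed = 1L) {
  if (is.unsorted(switchTimes) || any(switchTimes <= 0) ||
      any(switchTimes >= durationSec))
    stop("switchTimes must be increasing and inside (0, durationSec)")
  dt <- 10
  tt <- seq(0, durationSec - dt, by = dt)
  # state: FALSE = towards (SCN low, SWA rising), TRUE = away (SCN high)
  state <- (findInterval(tt, switchTimes) %% 2L) == 1L
  level <- 100 + amplitude * ifelse(state, 1, -1)
  baseline <- 10 * sin(2 * pi * tt / durationSec)
  swa <- numeric(length(tt))
  swaTarget <- ifelse(state, 0, 150)
  for (i in seq_along(tt)[-1])
    swa[i] <- swa[i - 1] + coupling * dt * (swaTarget[i] - swa[i - 1])
  withSeed(seed, {
    scnNoise <- stats::rnorm(length(tt), 0, noiseSd)
    swaNoise <- stats::rnorm(length(tt), 0, noiseSd)
  })
  list(scn = binTrace(tt, level + baseline + scnNoise, binWidth = 60),
       swa = binTrace(tt, pmax(swa + swaNoise, 0), binWidth = 60),
       threshold = 100, schedule = switchTimes)
}

#' Generate synthetic raw EEG following an episode model, with a hypnogram
#'
#' The EEG is a sum of three band-limited noise carriers (Butterworth
#' band-pass filtered white noise in 1-4, 12-15 and 18-25 Hz) whose
#' amplitude envelopes follow the square roots of the model's band-power
#' time courses, so that the spectral pipeline should recover the generating
#' curves. The accompanying hypnogram holds a wake lead-in, the NREM episode,
#' and a configurable REM tail, exercising segmentation.
#'
#' @param model An \linkS4class{EpisodeModel}.
#' @param fs Sampling rate in Hz (>= 64 so beta stays below Nyquist;
#'   default 128).
#' @param episodeMin Episode duration in minutes (default 40).
#' @param wakeMin Wake lead-in before sleep onset in minutes (default 2).
#' @param remMin REM tail after the episode in minutes (default 5).
#' @param seed Integer seed.
#' @return A list with \code{record} (\linkS4class{EEGRecord}),
#'   \code{hypnogram} (\linkS4class{Hypnogram}) and \code{model}.
#' @export
generateSyntheticEeg <- function(model, fs = 128, episodeMin = 40,
                                 wakeMin = 2, remMin = 5, seed = 1L) {
  stopifnot(is(model, "EpisodeModel"))
  if (fs < 64) stop("fs must be at least 64 Hz (beta band below Nyquist)")
  ptc <- predictPower(model, grid = seq(0.5, 99.5, by = 1))
  nEp <- as.integer(episodeMin * 60 * fs)
  tPct <- seq(0, 100, length.out = nEp)
  bands <- DEFAULT_BANDS
  env <- lapply(BAND_ORDER, function(b) {
    p <- stats::approx(binTimes(ptc), bandPower(ptc)[, b], xout = tPct,
                       rule = 2)$y
    sqrt(pmax(p, 0))
  })
  names(env) <- BAND_ORDER
  eeg <- withSeed(seed, {
    out <- numeric(nEp)
    for (b in BAND_ORDER) {
      bp <- signal::butter(3, bands[[b]] / (fs / 2), type = "pass")
      carrier <- signal::filtfilt(bp, stats::rnorm(nEp))
      carrier <- carrier / stats::sd(carrier)
      # unit-variance carrier scaled by the envelope: per-band variance
      # tracks the band-power target
      out <- out + env[[b]] * carrier
    }
    wake <- 20 * stats::rnorm(as.integer(wakeMin * 60 * fs))
    remC <- signal::filtfilt(signal::butter(3, c(4, 8) / (fs / 2), "pass"),
                             stats::rnorm(as.integer(remMin * 60 * fs)))
    c(wake, out, 5 * remC / stats::sd(remC))
  })
  nW <- as.integer(wakeMin * 3); nS <- as.integer(episodeMin * 3)
  nR <- as.integer(remMin * 3)
  stages <- c(rep("W", nW), rep("S2", 3), rep("S3", nS - 3), rep("REM", nR))
  list(record = eegRecord(eeg, rate = fs, label = "synthetic"),
       hypnogram = hypnogram(stages), model = model)
}
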