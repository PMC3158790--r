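#' @import methods
NULL

BAND_ORDER <- c("delta", "sigma", "beta")

#' Firing-mode transition probabilities
#'
#' Holds the four-element probability vector governing the shapes of the
#' towards and away time-course curves: beta->sigma and sigma->delta for the
#' sleep-deepening (towards) phase, delta->sigma and sigma->beta for the
#' sleep-lightening (away) phase. The unit of time is 1\% of the NREM episode
#' duration, so each entry is a transition probability per 1\% of episode.
#'
#' @slot probs Named numeric vector of length 4 with names
#'   \code{betaSigma}, \code{sigmaDelta}, \code{deltaSigma},
#'   \code{sigmaBeta}; each value strictly inside (0, 1).
#'
#' @seealso [transitionProbabilities()]
#' @exportClass TransitionProbabilities
setClass("TransitionProbabilities",
  representation(probs = "numeric"),
  validity = function(object) {
    p <- object@probs
    if (length(p) != 4L ||
        !identical(names(p), c("betaSigma", "sigmaDelta", "deltaSigma", "sigmaBeta")))
      return("probs must be named betaSigma, sigmaDelta, deltaSigma, sigmaBeta")
    if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1))
      return("all transition probabilities must lie strictly in (0, 1)")
    TRUE
  })

#' Construct a TransitionProbabilities object
#'
#' The defaults are the common probability set found to fit all NREM episodes
#' of all subjects: P = (0.13, 0.131, 0.2, 0.6) per 1\% of episode duration.
#'
#' @param betaSigma Probability per unit time of a beta->sigma mode transition
#'   (towards phase, first step).
#' @param sigmaDelta Probability of a sigma->delta transition (towards phase,
#'   second step).
#' @param deltaSigma Probability of a delta->sigma transition (away phase,
#'   first step).
#' @param sigmaBeta Probability of a sigma->beta transition (away phase,
#'   second step).
#' @return A \linkS4class{TransitionProbabilities} object.
#' @examples
#' transitionProbabilities()
#' transitionProbabilities(0.2, 0.25, 0.3, 0.5)
#' @export
transitionProbabilities <- function(betaSigma = 0.13, sigmaDelta = 0.131,
                                    deltaSigma = 0.2, sigmaBeta = 0.6) {
  new("TransitionProbabilities",
      probs = c(betaSigma = unname(betaSigma), sigmaDelta = unname(sigmaDelta),
                deltaSigma = unname(deltaSigma), sigmaBeta = unname(sigmaBeta)))
}

#' @describeIn transitionProbabilities Extract the named length-4 probability
#'   vector.
#' @param x A \code{TransitionProbabilities} object.
#' @export
probVector <- function(x) {
  stopifnot(is(x, "TransitionProbabilities"))
  x@probs
}

#' Phase plan: switchover times partitioning an episode
#'
#' An NREM episode is an alternation of towards (sleep-deepening) and away
#' (sleep-lightening) phases. The plan stores the interior switchover times,
#' in percent of episode duration, at which the dynamics flip between the
#' forward cascade (beta->sigma->delta) and the reverse cascade
#' (delta->sigma->beta). Phases alternate starting from \code{firstPhase} at
#' time 0; the episode spans [0, 100].
#'
#' @slot switchTimes Strictly increasing numeric vector of interior switchover
#'   times in (0, 100). May be empty (single-phase episode).
#' @slot firstPhase Either \code{"towards"} or \code{"away"}.
#'
#' @seealso [phasePlan()], [phaseIntervals()], [taCount()]
#' @exportClass PhasePlan
setClass("PhasePlan",
  representation(switchTimes = "numeric", firstPhase = "character"),
  validity = function(object) {
    s <- object@switchTimes
    if (length(s) && (any(!is.finite(s)) || any(s <= 0) || any(s >= 100)))
      return("switchTimes must lie strictly inside (0, 100)")
    if (length(s) > 1 && any(diff(s) <= 0))
      return("switchTimes must be strictly increasing")
    if (length(object@firstPhase) != 1L ||
        !object@firstPhase %in% c("towards", "away"))
      return("firstPhase must be 'towards' or 'away'")
    TRUE
  })

#' Construct a PhasePlan
#'
#' @param switchTimes Strictly increasing interior switchover times in
#'   (0, 100), percent of episode duration.
#' @param firstPhase Phase active at time 0 (default \code{"towards"}).
#' @return A \linkS4class{PhasePlan}.
#' @examples
#' phasePlan(c(30, 55, 80))            # towards/away/towards/away
#' taCount(phasePlan(c(30, 55, 80)))   # 2 full towards-away cycles started
#' @export
phasePlan <- function(switchTimes = numeric(0), firstPhase = "towards") {
  new("PhasePlan", switchTimes = as.numeric(switchTimes), firstPhase = firstPhase)
}

#' Phase intervals of a plan
#'
#' @param plan A \linkS4class{PhasePlan}.
#' @return A data.frame with columns \code{start}, \code{end}, \code{phase}
#'   covering [0, 100] with alternating towards/away phases.
#' @export
phaseIntervals <- function(plan) {
  stopifnot(is(plan, "PhasePlan"))
  bounds <- c(0, plan@switchTimes, 100)
  n <- length(bounds) - 1L
  phases <- rep(c("towards", "away"), length.out = n)
  if (plan@firstPhase == "away")
    phases <- rep(c("away", "towards"), length.out = n)
  data.frame(start = bounds[-length(bounds)], end = bounds[-1], phase = phases,
             stringsAsFactors = FALSE)
}

#' Number of towards-away (TA) cycles in a plan
#'
#' A TA cycle is a move towards deep sleep followed (or begun) within the
#' episode; the count equals the number of towards phases in the plan.
#'
#' @param plan A \linkS4class{PhasePlan}.
#' @return Integer TA cycle count.
#' @export
taCount <- function(plan) {
  sum(phaseIntervals(plan)$phase == "towards")
}

#' Firing-mode occupancy trajectory
#'
#' Numbers (or fractions, when normalised to the generating population size)
#' of generating-population neurons in each firing mode at one or more time
#' points. Time is in percent of episode duration.
#'
#' @slot time Numeric vector of time points.
#' @slot beta,sigma,delta Numeric vectors (same length as \code{time}) of
#'   occupancies; all non-negative.
#' @exportClass ModeOccupancy
setClass("ModeOccupancy",
  representation(time = "numeric", beta = "numeric", sigma = "numeric",
                 delta = "numeric"),
  validity = function(object) {
    n <- length(object@time)
    if (length(object@beta) != n || length(object@sigma) != n ||
        length(object@delta) != n)
      return("time, beta, sigma, delta must have equal length")
    v <- c(object@beta, object@sigma, object@delta)
    if (any(!is.finite(v))) return("occupancies must be finite")
    if (any(v < -1e-9)) return("occupancies must be non-negative")
    TRUE
  })

#' Construct a ModeOccupancy
#'
#' @param beta,sigma,delta Occupancy of each firing mode (scalars or vectors).
#' @param time Time points in percent of episode duration (default 0).
#' @return A \linkS4class{ModeOccupancy}.
#' @examples
#' modeOccupancy(beta = 1, sigma = 0, delta = 0)  # episode onset
#' @export
modeOccupancy <- function(beta, sigma, delta, time = 0) {
  n <- max(length(beta), length(sigma), length(delta), length(time))
  new("ModeOccupancy", time = rep_len(as.numeric(time), n),
      beta = rep_len(as.numeric(beta), n),
      sigma = rep_len(as.numeric(sigma), n),
      delta = rep_len(as.numeric(delta), n))
}

#' @describeIn modeOccupancy Coerce to a data.frame with columns time, beta,
#'   sigma, delta.
#' @param x A \code{ModeOccupancy}.
#' @export
occupancyFrame <- function(x) {
  stopifnot(is(x, "ModeOccupancy"))
  data.frame(time = x@time, beta = x@beta, sigma = x@sigma, delta = x@delta)
}

#' Full generative model of one NREM episode
#'
#' Combines the transition probabilities, the phase plan, the initial mode
#' occupancy and the mapping from occupancy to EEG band power (one
#' multiplicative normalisation factor per band, plus an additive constant
#' background beta component).
#'
#' @slot probabilities A \linkS4class{TransitionProbabilities}.
#' @slot plan A \linkS4class{PhasePlan}.
#' @slot initialOccupancy Named numeric (beta, sigma, delta) at time 0.
#' @slot bandScales Named numeric (delta, sigma, beta), all > 0, in uV^2 per
#'   unit occupancy.
#' @slot betaBias Constant background beta power in uV^2, >= 0.
#' @exportClass EpisodeModel
setClass("EpisodeModel",
  representation(probabilities = "TransitionProbabilities", plan = "PhasePlan",
                 initialOccupancy = "numeric", bandScales = "numeric",
                 betaBias = "numeric"),
  validity = function(object) {
    io <- object@initialOccupancy
    if (!identical(names(io), c("beta", "sigma", "delta")))
      return("initialOccupancy must be named beta, sigma, delta")
    if (any(!is.finite(io)) || any(io < 0))
      return("initialOccupancy must be non-negative and finite")
    bs <- object@bandScales
    if (!identical(names(bs), BAND_ORDER))
      return("bandScales must be named delta, sigma, beta")
    if (any(!is.finite(bs)) || any(bs <= 0))
      return("bandScales must be positive")
    if (length(object@betaBias) != 1L || !is.finite(object@betaBias) ||
        object@betaBias < 0)
      return("betaBias must be a single non-negative number")
    TRUE
  })

#' Construct an EpisodeModel
#'
#' @param probabilities A \linkS4class{TransitionProbabilities}; default the
#'   common fitted set.
#' @param plan A \linkS4class{PhasePlan}.
#' @param initialOccupancy Numeric length 3 (beta, sigma, delta) at episode
#'   start; default all neurons in beta mode, population normalised to 1.
#' @param bandScales Numeric length 3 (delta, sigma, beta) multiplicative
#'   factors mapping occupancy to band power in uV^2.
#' @param betaBias Constant background beta power in uV^2 (default 2).
#' @return An \linkS4class{EpisodeModel}.
#' @examples
#' episodeModel(plan = phasePlan(c(40, 70)))
#' @export
episodeModel <- function(probabilities = transitionProbabilities(),
                         plan = phasePlan(),
                         initialOccupancy = c(beta = 1, sigma = 0, delta = 0),
                         bandScales = c(delta = 1, sigma = 1, beta = 1),
                         betaBias = 2) {
  io <- as.numeric(initialOccupancy); names(io) <- c("beta", "sigma", "delta")
  bs <- as.numeric(bandScales); names(bs) <- BAND_ORDER
  new("EpisodeModel", probabilities = probabilities, plan = plan,
      initialOccupancy = io, bandScales = bs, betaBias = as.numeric(betaBias))
}

#' Binned band-power time course of one NREM episode
#'
#' Episode duration is normalised to 100\% and average power in each band is
#' held on an equally spaced bin grid (by convention 50 bins of 2\%). Missing
#' bins (artefact-masked data) are NA.
#'
#' @slot time Bin centre times in percent of episode duration, equally spaced.
#' @slot power Numeric matrix, rows = bins, columns \code{delta},
#'   \code{sigma}, \code{beta}, in uV^2; NA marks a missing bin.
#' @slot binWidth Bin width in percent.
#' @exportClass PowerTimeCourse
setClass("PowerTimeCourse",
  representation(time = "numeric", power = "matrix", binWidth = "numeric"),
  validity = function(object) {
    if (!identical(colnames(object@power), BAND_ORDER))
      return("power columns must be delta, sigma, beta")
    if (nrow(object@power) != length(object@time))
      return("power rows must match time length")
    if (length(object@time) > 1) {
      d <- diff(object@time)
      if (any(abs(d - d[1]) > 1e-8)) return("bins must be equally spaced")
      if (d[1] <= 0) return("time must be increasing")
    }
    if (any(object@power[!is.na(object@power)] < 0))
      return("power must be non-negative")
    TRUE
  })

#' Construct a PowerTimeCourse
#'
#' @param time Bin centre times (percent of episode), equally spaced.
#' @param delta,sigma,beta Numeric vectors of band power per bin (uV^2);
#'   NA = missing bin.
#' @param binWidth Bin width in percent; default inferred from \code{time}.
#' @return A \linkS4class{PowerTimeCourse}.
#' @export
powerTimeCourse <- function(time, delta, sigma, beta, binWidth = NULL) {
  pw <- cbind(delta = as.numeric(delta), sigma = as.numeric(sigma),
              beta = as.numeric(beta))
  if (is.null(binWidth))
    binWidth <- if (length(time) > 1) diff(time)[1] else 2
  new("PowerTimeCourse", time = as.numeric(time), power = pw,
      binWidth = as.numeric(binWidth))
}

#' @describeIn powerTimeCourse Band power matrix (bins x delta/sigma/beta).
#' @param x A \code{PowerTimeCourse}.
#' @export
bandPower <- function(x) {
  stopifnot(is(x, "PowerTimeCourse"))
  x@power
}

#' @describeIn powerTimeCourse Bin centre times in percent.
#' @export
binTimes <- function(x) {
  stopifnot(is(x, "PowerTimeCourse"))
  x@time
}

#' Result of fitting the cascade model to one episode
#'
#' @slot model The fitted \linkS4class{EpisodeModel}.
#' @slot r2Band Named numeric (delta, sigma, beta): per-band coefficient of
#'   determination in percent.
#' @slot r2Overall Overall R^2 (percent), Fisher-z combination of the bands.
#' @slot quality Quality class: \code{"VG"} (>= 60), \code{"G"} (40-60),
#'   \code{"F"} (19-40) or \code{"BF"} (below fair, < 19).
#' @slot residuals Matrix of per-bin residuals (observed - fitted) per band.
#' @slot taCount Integer, number of towards-away cycles in the fitted plan.
#' @slot converged Logical; FALSE if the switchover refinement hit its
#'   iteration cap.
#' @slot data The \linkS4class{PowerTimeCourse} that was fitted.
#' @exportClass FitResult
setClass("FitResult",
  representation(model = "EpisodeModel", r2Band = "numeric",
                 r2Overall = "numeric", quality = "character",
                 residuals = "matrix", taCount = "integer",
                 converged = "logical", data = "PowerTimeCourse"),
  validity = function(object) {
    if (!identical(names(object@r2Band), BAND_ORDER))
      return("r2Band must be named delta, sigma, beta")
    if (any(object@r2Band > 100 + 1e-9, na.rm = TRUE))
      return("R^2 cannot exceed 100%")
    if (length(object@r2Overall) != 1L || object@r2Overall > 100 + 1e-9)
      return("r2Overall must be a single value <= 100")
    if (!object@quality %in% c("VG", "G", "F", "BF"))
      return("quality must be VG, G, F or BF")
    TRUE
  })

#' @describeIn fitEpisode Fitted episode model of a fit result.
#' @param fit A \linkS4class{FitResult}.
#' @export
fittedModel <- function(fit) {
  stopifnot(is(fit, "FitResult"))
  fit@model
}

#' @describeIn fitEpisode Per-band and overall goodness of fit (percent).
#' @export
r2Values <- function(fit) {
  stopifnot(is(fit, "FitResult"))
  c(fit@r2Band, overall = fit@r2Overall)
}

#' Raw single-channel EEG record
#'
#' @slot samples Numeric vector of EEG samples in uV.
#' @slot rate Sampling rate in Hz.
#' @slot label Channel label.
#' @exportClass EEGRecord
setClass("EEGRecord",
  representation(samples = "numeric", rate = "numeric", label = "character"),
  validity = function(object) {
    if (length(object@rate) != 1L || !is.finite(object@rate) ||
        object@rate <= 0)
      return("rate must be a single positive number")
    if (any(!is.finite(object@samples))) return("samples must be finite")
    TRUE
  })

#' Construct an EEGRecord
#'
#' @param samples EEG samples in uV.
#' @param rate Sampling rate in Hz (default 256).
#' @param label Channel label.
#' @return An \linkS4class{EEGRecord}.
#' @export
eegRecord <- function(samples, rate = 256, label = "EEG") {
  new("EEGRecord", samples = as.numeric(samples), rate = as.numeric(rate),
      label = label)
}

HYPNO_CODES <- c("W", "REM", "S1", "S2", "S3", "S4", "MT", "U")

#' Hypnogram: visually scored sleep stages in 20-s epochs
#'
#' @slot stages Character vector of stage codes, one per 20-s epoch, from
#'   W, REM, S1, S2, S3, S4, MT (movement time), U (unscored).
#' @slot lightsOff,lightsOn 1-based epoch indices of lights-off and lights-on.
#' @exportClass Hypnogram
setClass("Hypnogram",
  representation(stages = "character", lightsOff = "integer",
                 lightsOn = "integer"),
  validity = function(object) {
    if (!all(object@stages %in% HYPNO_CODES))
      return(paste("stage codes must be in:", paste(HYPNO_CODES, collapse = " ")))
    if (object@lightsOff < 1L || object@lightsOff > length(object@stages))
      return("lightsOff out of range")
    TRUE
  })

#' Construct a Hypnogram
#'
#' @param stages Stage codes (W, REM, S1-S4, MT, U), one per 20-s epoch.
#' @param lightsOff 1-based epoch index of lights-off (default 1).
#' @param lightsOn 1-based epoch index of lights-on (default last epoch).
#' @return A \linkS4class{Hypnogram}.
#' @export
hypnogram <- function(stages, lightsOff = 1L, lightsOn = length(stages)) {
  new("Hypnogram", stages = as.character(stages),
      lightsOff = as.integer(lightsOff), lightsOn = as.integer(lightsOn))
}

#' Uniformly binned activity trace
#'
#' Used for SCN multi-unit activity and slow-wave activity (SWA) time
#' courses, expressed e.g. as percent of the mean NREM-sleep level.
#'
#' @slot time Bin start times (seconds), uniformly spaced.
#' @slot binWidth Bin width in seconds (default 60: one-minute bins, each the
#'   mean of six 10-s epochs).
#' @slot values Mean value per bin; NA for empty bins.
#' @exportClass ActivityTrace
setClass("ActivityTrace",
  representation(time = "numeric", binWidth = "numeric", values = "numeric"),
  validity = function(object) {
    if (length(object@time) != length(object@values))
      return("time and values must have equal length")
    if (length(object@time) > 1) {
      d <- diff(object@time)
      if (any(abs(d - object@binWidth) > 1e-6 * object@binWidth))
        return("bins must be uniform with spacing binWidth")
    }
    if (any(is.infinite(object@values))) return("values must be finite or NA")
    TRUE
  })

#' Construct an ActivityTrace
#'
#' @param time Bin start times in seconds (uniform spacing).
#' @param values Bin values.
#' @param binWidth Bin width in seconds; default inferred.
#' @return An \linkS4class{ActivityTrace}.
#' @export
activityTrace <- function(time, values, binWidth = NULL) {
  if (is.null(binWidth))
    binWidth <- if (length(time) > 1) diff(time)[1] else 60
  new("ActivityTrace", time = as.numeric(time), binWidth = as.numeric(binWidth),
      values = as.numeric(values))
}

#' @describeIn activityTrace Bin centre times of a trace.
#' @param x An \code{ActivityTrace}.
#' @export
binCentres <- function(x) {
  stopifnot(is(x, "ActivityTrace"))
  x@time + x@binWidth / 2
}

#' Temporal alignment report between crossing and transition events
#'
#' @slot matched Number of reference transitions matched one-to-one by a
#'   threshold crossing within tolerance.
#' @slot total Number of reference transitions.
#' @slot tolerance Matching tolerance in seconds.
#' @slot pairs data.frame of matched pairs (reference time, crossing time,
#'   absolute offset).
#' @slot rate Match rate in percent (NA when total is 0).
#' @exportClass AlignmentReport
setClass("AlignmentReport",
  representation(matched = "integer", total = "integer", tolerance = "numeric",
                 pairs = "data.frame", rate = "numeric"),
  validity = function(object) {
    if (object@matched > object@total) return("matched cannot exceed total")
    if (object@tolerance < 0) return("tolerance must be non-negative")
    TRUE
  })

#' @describeIn alignEvents Match rate (percent) of an alignment report.
#' @param report An \linkS4class{AlignmentReport}.
#' @export
matchRate <- function(report) {
  stopifnot(is(report, "AlignmentReport"))
  report@rate
}
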