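#' @describeIn transitionProbabilities Display method.
#' @param object A \code{TransitionProbabilities}.
#' @export
setMethod("show", "TransitionProbabilities", function(object) {
  p <- object@probs
  cat("TransitionProbabilities (per 1% of episode duration)\n")
  cat(sprintf("  towards: beta->sigma %.4g, sigma->delta %.4g\n",
              p["betaSigma"], p["sigmaDelta"]))
  cat(sprintf("  away:    delta->sigma %.4g, sigma->beta %.4g\n",
              p["deltaSigma"], p["sigmaBeta"]))
})

#' @describeIn phasePlan Display method.
#' @param object A \code{PhasePlan}.
#' @export
setMethod("show", "PhasePlan", function(object) {
  iv <- phaseIntervals(object)
  cat(sprintf("PhasePlan: %d phase(s), %d towards-away cycle(s)\n",
              nrow(iv), taCount(object)))
  cat(sprintf("  %s [%.1f, %.1f]%%\n", format(iv$phase, width = 7),
              iv$start, iv$end), sep = "")
})

#' @describeIn episodeModel Display method.
#' @param object An \code{EpisodeModel}.
#' @export
setMethod("show", "EpisodeModel", function(object) {
  cat("EpisodeModel\n")
  show(object@probabilities)
  show(object@plan)
  cat(sprintf("  band scales (uV^2/unit): delta %.3g, sigma %.3g, beta %.3g; beta bias %.3g uV^2\n",
              object@bandScales["delta"], object@bandScales["sigma"],
              object@bandScales["beta"], object@betaBias))
})

#' @describeIn modeOccupancy Display method.
#' @param object A \code{ModeOccupancy}.
#' @export
setMethod("show", "ModeOccupancy", function(object) {
  n <- length(object@time)
  cat(sprintf("ModeOccupancy: %d time point(s)\n", n))
  print(utils::head(occupancyFrame(object), 5))
  if (n > 5) cat("  ...\n")
})

#' @describeIn powerTimeCourse Display method.
#' @param object A \code{PowerTimeCourse}.
#' @export
setMethod("show", "PowerTimeCourse", function(object) {
  nmiss <- colSums(is.na(object@power))
  cat(sprintf("PowerTimeCourse: %d bins of %.3g%%; missing bins delta %d, sigma %d, beta %d\n",
              nrow(object@power), object@binWidth,
              nmiss["delta"], nmiss["sigma"], nmiss["beta"]))
})

#' @describeIn fitEpisode Display method.
#' @param object A \code{FitResult}.
#' @export
setMethod("show", "FitResult", function(object) {
  cat(sprintf("FitResult: overall R^2 = %.1f%% (%s), %d TA cycle(s)%s\n",
              object@r2Overall, object@quality, object@taCount,
              if (object@converged) "" else " [not converged]"))
  cat(sprintf("  per-band R^2: delta %.1f, sigma %.1f, beta %.1f\n",
              object@r2Band["delta"], object@r2Band["sigma"],
              object@r2Band["beta"]))
})

#' @describeIn eegRecord Display method.
#' @param object An \code{EEGRecord}.
#' @export
setMethod("show", "EEGRecord", function(object) {
  cat(sprintf("EEGRecord '%s': %d samples at %g Hz (%.1f min)\n", object@label,
              length(object@samples), object@rate,
              length(object@samples) / object@rate / 60))
})

#' @describeIn hypnogram Display method.
#' @param object A \code{Hypnogram}.
#' @export
setMethod("show", "Hypnogram", function(object) {
  cat(sprintf("Hypnogram: %d epochs of 20 s (%.1f h); lights off at epoch %d\n",
              length(object@stages), length(object@stages) / 180,
              object@lightsOff))
  print(table(factor(object@stages, levels = HYPNO_CODES)))
})

#' @describeIn activityTrace Display method.
#' @param object An \code{ActivityTrace}.
#' @export
setMethod("show", "ActivityTrace", function(object) {
  cat(sprintf("ActivityTrace: %d bins of %g s (%.1f min)\n",
              length(object@values), object@binWidth,
              length(object@values) * object@binWidth / 60))
})

#' @describeIn alignEvents Display method.
#' @param object An \code{AlignmentReport}.
#' @export
setMethod("show", "AlignmentReport", function(object) {
  cat(sprintf("AlignmentReport: %d/%d reference transitions matched (%.1f%%) at tolerance %g s\n",
              object@matched, object@total,
              ifelse(is.na(object@rate), NaN, object@rate), object@tolerance))
})
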