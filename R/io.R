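# Readers and writers for the delimited-text and JSON formats the pipeline
# consumes and produces, YAML run configuration, and the end-to-end pipeline.

# Header-first delimited text, comma or tab auto-detected.
.readDelim <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    na.strings = c("NA", ""))
}

#' Read and write band-power time courses
#'
#' Delimited text (comma or tab), one row per bin, columns \code{time_pct},
#' \code{delta}, \code{sigma}, \code{beta}; empty cells are missing bins.
#' Writer/reader round trips are lossless.
#'
#' @param path File path.
#' @return \code{readPowerTimeCourse}: a \linkS4class{PowerTimeCourse}.
#' @export
readPowerTimeCourse <- function(path) {
  df <- .readDelim(path)
  need <- c("time_pct", "delta", "sigma", "beta")
  if (!all(need %in% names(df)))
    stop("expected columns time_pct, delta, sigma, beta in ", path)
  powerTimeCourse(time = df$time_pct, delta = df$delta, sigma = df$sigma,
                  beta = df$beta)
}

#' @rdname readPowerTimeCourse
#' @param x A \linkS4class{PowerTimeCourse}.
#' @export
writePowerTimeCourse <- function(x, path) {
  stopifnot(is(x, "PowerTimeCourse"))
  df <- data.frame(time_pct = x@time, delta = x@power[, "delta"],
                   sigma = x@power[, "sigma"], beta = x@power[, "beta"])
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE,
                     na = "")
  invisible(path)
}

#' Read and write hypnograms
#'
#' One stage code per line (20-s epochs), after comment-style header lines
#' \code{# lights_off: <epoch>} and \code{# lights_on: <epoch>} (1-based).
#'
#' @param path File path.
#' @return \code{readHypnogram}: a \linkS4class{Hypnogram}.
#' @export
readHypnogram <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  getNum <- function(key, default) {
    hit <- grep(paste0("^#\\s*", key, "\\s*:"), hdr, value = TRUE)
    if (!length(hit)) return(default)
    as.integer(sub(".*:\\s*", "", hit[1]))
  }
  stages <- trimws(grep("^#", lines, value = TRUE, invert = TRUE))
  stages <- stages[nzchar(stages)]
  bad <- which(!stages %in% HYPNO_CODES)
  if (length(bad))
    stop("invalid stage code at data line ", bad[1], ": '", stages[bad[1]], "'")
  hypnogram(stages, lightsOff = getNum("lights_off", 1L),
            lightsOn = getNum("lights_on", length(stages)))
}

#' @rdname readHypnogram
#' @param hyp A \linkS4class{Hypnogram}.
#' @export
writeHypnogram <- function(hyp, path) {
  stopifnot(is(hyp, "Hypnogram"))
  writeLines(c(sprintf("# lights_off: %d", hyp@lightsOff),
               sprintf("# lights_on: %d", hyp@lightsOn), hyp@stages), path)
  invisible(path)
}

#' Read and write activity traces
#'
#' Two-column delimited text: \code{time_s}, \code{value}.
#'
#' @param path File path.
#' @return \code{readActivityTrace}: an \linkS4class{ActivityTrace}.
#' @export
readActivityTrace <- function(path) {
  df <- .readDelim(path)
  if (!all(c("time_s", "value") %in% names(df)))
    stop("expected columns time_s, value in ", path)
  activityTrace(time = df$time_s, values = df$value)
}

#' @rdname readActivityTrace
#' @param x An \linkS4class{ActivityTrace}.
#' @export
writeActivityTrace <- function(x, path) {
  stopifnot(is(x, "ActivityTrace"))
  utils::write.table(data.frame(time_s = x@time, value = x@values), path,
                     sep = "\t", row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a subject/episode cohort table
#'
#' Delimited text with columns \code{subject}, \code{nrem}, \code{ta},
#' \code{r2}.
#'
#' @param path File path.
#' @return A data.frame with those columns, checked for validity.
#' @export
readSubjectEpisodeTable <- function(path) {
  df <- .readDelim(path)
  need <- c("subject", "nrem", "ta", "r2")
  if (!all(need %in% names(df)))
    stop("expected columns subject, nrem, ta, r2 in ", path)
  bad <- which(!is.finite(df$r2) | df$r2 <= 0 | df$r2 >= 100)
  if (length(bad)) stop("R^2 out of (0,100) at data row ", bad[1])
  if (any(df$ta < 1 | df$ta != round(df$ta)))
    stop("ta must be positive integers")
  df[need]
}

#' Serialise and restore a fit result as JSON
#'
#' The document carries the fitted parameters (probabilities, switchover
#' times, band scales, beta bias), the per-band and overall R^2, the quality
#' class and the TA count. \code{readFitResult} restores the parameter set
#' as a list (not the full object: residuals and data stay with the R
#' session).
#'
#' @param fit A \linkS4class{FitResult}.
#' @param path Output path.
#' @return \code{writeFitResult}: \code{path}, invisibly.
#' @export
writeFitResult <- function(fit, path) {
  stopifnot(is(fit, "FitResult"))
  doc <- list(
    probabilities = as.list(probVector(fit@model@probabilities)),
    switchover_times = fit@model@plan@switchTimes,
    first_phase = fit@model@plan@firstPhase,
    band_scales = as.list(fit@model@bandScales),
    beta_bias = fit@model@betaBias,
    r2_band = as.list(fit@r2Band),
    r2_overall = fit@r2Overall,
    quality = fit@quality,
    ta_count = fit@taCount,
    converged = fit@converged)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeFitResult
#' @export
readFitResult <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Write an alignment report as JSON
#'
#' @param report An \linkS4class{AlignmentReport}.
#' @param path Output path.
#' @export
writeAlignmentReport <- function(report, path) {
  stopifnot(is(report, "AlignmentReport"))
  jsonlite::write_json(list(matched = report@matched, total = report@total,
                            tolerance = report@tolerance, rate = report@rate,
                            pairs = report@pairs),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

RUN_CONFIG_KEYS <- c("eeg", "hypnogram", "out", "bands", "probabilities",
                     "beta_bias", "seed", "max_iter", "artefact_k")

#' Read and validate a YAML run configuration
#'
#' Recognised keys: \code{eeg}, \code{hypnogram}, \code{out}, \code{bands}
#' (named list of two-element Hz ranges), \code{probabilities} (length-4
#' vector), \code{beta_bias}, \code{seed}, \code{max_iter},
#' \code{artefact_k}. Unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return A validated named list.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), RUN_CONFIG_KEYS)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  if (!is.null(cfg$probabilities) && length(cfg$probabilities) != 4L)
    stop("probabilities must have 4 elements")
  if (!is.null(cfg$beta_bias) && cfg$beta_bias < 0)
    stop("beta_bias must be non-negative")
  cfg
}

#' Run the full single-subject pipeline
#'
#' Spectra -> artefact masking -> episode segmentation -> per-episode
#' rebinning and model fitting -> summary. Each stage failure halts with a
#' diagnostic naming the stage. Deterministic given (inputs, config).
#'
#' @param record An \linkS4class{EEGRecord}.
#' @param hyp A \linkS4class{Hypnogram}.
#' @param config Optional list as from [readRunConfig()].
#' @param outDir Optional directory: per-episode fit JSONs and a summary
#'   JSON are written there.
#' @return A list with \code{fits} (per-episode \linkS4class{FitResult}),
#'   \code{sleep} (latency/efficiency) and \code{summary} (data.frame of
#'   per-episode R^2, quality, TA).
#' @export
runPipeline <- function(record, hyp, config = list(), outDir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  bands <- config$bands %||% DEFAULT_BANDS
  fc <- fitConfig(
    probabilities = if (is.null(config$probabilities))
      transitionProbabilities()
    else do.call(transitionProbabilities, as.list(config$probabilities)),
    betaBias = config$beta_bias %||% 2)
  courses <- stage("spectra+segmentation",
                   episodePowerCourses(record, hyp, bands = bands))
  fits <- stage("fitting", lapply(courses, fitEpisode, config = fc))
  sleep <- stage("sleep-statistics", sleepStatistics(hyp))
  summary <- data.frame(nrem = seq_along(fits),
                        r2 = vapply(fits, function(f) f@r2Overall, numeric(1)),
                        quality = vapply(fits, function(f) f@quality,
                                         character(1)),
                        ta = vapply(fits, function(f) f@taCount, integer(1)))
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_along(fits))
      writeFitResult(fits[[i]], file.path(outDir, sprintf("fit_nrem%d.json", i)))
    jsonlite::write_json(list(sleep = sleep, episodes = summary),
                         file.path(outDir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(fits = fits, sleep = sleep, summary = summary)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
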