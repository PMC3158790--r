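# Threshold flip-flop analysis: threshold crossings of a binned activity
# trace (e.g. SCN multi-unit firing) scored for temporal alignment with the
# towards/away state transitions of a second trace (e.g. SWA).

#' Bin an irregular sample series onto a uniform grid
#'
#' Bin value = mean of the samples falling in the bin; empty bins are NA.
#' The default 60-s bins correspond to one-minute activity points, each the
#' mean of six 10-s epochs.
#'
#' @param time Sample times in seconds (sorted).
#' @param values Sample values.
#' @param binWidth Bin width in seconds (default 60).
#' @param origin Start of the first bin (default \code{floor(min(time))}
#'   aligned to the bin width).
#' @return An \linkS4class{ActivityTrace}.
#' @export
binTrace <- function(time, values, binWidth = 60, origin = NULL) {
  if (is.unsorted(time)) stop("time must be sorted")
  if (is.null(origin)) origin <- floor(min(time) / binWidth) * binWidth
  idx <- floor((time - origin) / binWidth)
  nb <- max(idx) + 1L
  means <- tapply(values, factor(idx, levels = 0:(nb - 1L)),
                  function(z) mean(z, na.rm = TRUE))
  v <- as.numeric(means); v[is.nan(v)] <- NA_real_
  activityTrace(time = origin + binWidth * (0:(nb - 1L)), values = v,
                binWidth = binWidth)
}

#' Detect threshold crossings of an activity trace
#'
#' Emits an event wherever the sign of (value - threshold) changes between
#' consecutive bins, with the crossing time linearly interpolated between the
#' two bin centres. Events alternate strictly in direction. Crossing times
#' carry the binning's intrinsic precision of about half a bin width, which
#' is also the default matching tolerance downstream.
#'
#' @param trace An \linkS4class{ActivityTrace}.
#' @param threshold A single value, or a vector with one threshold per bin
#'   (a slowly varying threshold curve).
#' @return A data.frame with columns \code{time} (s) and \code{direction}
#'   (\code{"up"} or \code{"down"}); zero rows when the trace never crosses.
#' @examples
#' tr <- activityTrace(seq(0, 540, by = 60), c(1, 1, 5, 5, 1, 1, 5, 5, 1, 1))
#' detectCrossings(tr, 3)
#' @export
detectCrossings <- function(trace, threshold) {
  stopifnot(is(trace, "ActivityTrace"))
  v <- trace@values
  th <- if (length(threshold) == 1L) rep(threshold, length(v)) else threshold
  if (length(th) != length(v))
    stop("threshold must be scalar or match the trace grid")
  d <- v - th
  ok <- which(!is.na(d))
  if (length(ok) < 2L) return(data.frame(time = numeric(0), direction = character(0)))
  tc <- binCentres(trace)[ok]; d <- d[ok]
  s <- sign(d)
  for (i in seq_along(s)) if (s[i] == 0 && i > 1) s[i] <- s[i - 1]
  times <- numeric(0); dirs <- character(0)
  for (i in seq_len(length(d) - 1L)) {
    if (s[i] != 0 && s[i + 1] != 0 && s[i] != s[i + 1]) {
      tstar <- tc[i] + (tc[i + 1] - tc[i]) * (0 - d[i]) / (d[i + 1] - d[i])
      times <- c(times, tstar)
      dirs <- c(dirs, if (s[i + 1] > 0) "up" else "down")
    }
  }
  data.frame(time = times, direction = dirs, stringsAsFactors = FALSE)
}

#' Detect towards/away state transitions in an SWA trace
#'
#' Reuses the switchover mechanics of the episode-fitting stage on an
#' arbitrary uniform grid: the trace is three-point smoothed and its
#' alternating peaks (start of an away phase, SWA beginning to fall) and
#' troughs (start of a towards phase) are returned.
#'
#' @param swa An \linkS4class{ActivityTrace} with at least 5 bins.
#' @param prominence Minimum swing between successive transitions as a
#'   fraction of the trace range (default 0.1), pruning noise wiggles.
#' @return A data.frame with columns \code{time} (s, bin centre) and
#'   \code{direction} (\code{"away-start"} at peaks, \code{"towards-start"}
#'   at troughs); zero rows for a monotone trace.
#' @export
detectStateTransitions <- function(swa, prominence = 0.1) {
  stopifnot(is(swa, "ActivityTrace"))
  if (sum(!is.na(swa@values)) < 5L) stop("need at least 5 non-missing bins")
  sm <- smooth3(swa@values)
  ex <- .alternatingExtrema(sm)
  ex <- .pruneExtrema(ex, sm, prominence * diff(range(sm, na.rm = TRUE)))
  # smoothing drags extrema of asymmetric rise/decay shapes off their bin;
  # re-centre each on the raw trace within one bin of the smoothed location
  n <- length(swa@values)
  ex$index <- vapply(seq_len(nrow(ex)), function(i) {
    w <- max(1L, ex$index[i] - 1L):min(n, ex$index[i] + 1L)
    v <- swa@values[w]
    if (all(is.na(v))) return(ex$index[i])
    if (ex$type[i] == 1L) w[which.max(v)] else w[which.min(v)]
  }, integer(1))
  data.frame(time = binCentres(swa)[ex$index],
             direction = ifelse(ex$type == 1L, "away-start", "towards-start"),
             stringsAsFactors = FALSE)
}

#' Score the temporal alignment of crossings against reference transitions
#'
#' Matches threshold-crossing events to reference state transitions
#' one-to-one, greedily by ascending absolute time difference, accepting only
#' pairs within the tolerance (default half a bin width, the stated timing
#' precision of binned data). The report carries the matched/total counts and
#' the match rate in percent.
#'
#' @param crossings data.frame with a \code{time} column (s), as from
#'   [detectCrossings()].
#' @param transitions data.frame with a \code{time} column (s), the reference
#'   events, as from [detectStateTransitions()].
#' @param tolerance Matching tolerance in seconds (>= 0).
#' @return An \linkS4class{AlignmentReport}. With an empty reference list the
#'   rate is NA (flagged, not an error).
#' @export
alignEvents <- function(crossings, transitions, tolerance = 30) {
  if (tolerance < 0) stop("tolerance must be non-negative")
  ct <- crossings$time; rt <- transitions$time
  pairs <- expand.grid(cross = seq_along(ct), ref = seq_along(rt))
  if (nrow(pairs)) {
    pairs$offset <- abs(ct[pairs$cross] - rt[pairs$ref])
    pairs <- pairs[pairs$offset <= tolerance, , drop = FALSE]
    pairs <- pairs[order(pairs$offset), , drop = FALSE]
  } else pairs$offset <- numeric(0)
  usedC <- logical(length(ct)); usedR <- logical(length(rt))
  keep <- logical(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    if (!usedC[pairs$cross[i]] && !usedR[pairs$ref[i]]) {
      keep[i] <- TRUE
      usedC[pairs$cross[i]] <- TRUE; usedR[pairs$ref[i]] <- TRUE
    }
  }
  pairs <- pairs[keep, , drop = FALSE]
  matched <- nrow(pairs)
  total <- length(rt)
  new("AlignmentReport", matched = as.integer(matched),
      total = as.integer(total), tolerance = as.numeric(tolerance),
      pairs = data.frame(referenceTime = rt[pairs$ref],
                         crossingTime = ct[pairs$cross],
                         offset = pairs$offset),
      rate = if (total == 0L) NA_real_ else 100 * matched / total)
}

#' Heuristic threshold estimate for a flip-flop trace
#'
#' Midpoint between the 10th and 90th percentile envelopes of the trace —
#' about half way between the lines enclosing most of the data points. A
#' heuristic, intended as a starting point when no threshold is supplied.
#'
#' @param trace An \linkS4class{ActivityTrace}.
#' @return A single threshold value.
#' @export
estimateThreshold <- function(trace) {
  stopifnot(is(trace, "ActivityTrace"))
  q <- stats::quantile(trace@values, c(0.1, 0.9), na.rm = TRUE, names = FALSE)
  mean(q)
}
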