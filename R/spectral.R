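# From raw single-channel EEG and a hypnogram to band-power time courses and
# standard sleep statistics: Hann-windowed FFT band powers in consecutive 4-s
# epochs, RMS-based artefact masking, 15-min-rule episode segmentation.

DEFAULT_BANDS <- list(delta = c(1, 4), sigma = c(12, 15), beta = c(18, 25))

#' Band power per consecutive 4-s epoch
#'
#' EEG power spectra in uV^2 are computed by FFT with a Hann window for
#' consecutive 4-s epochs, giving 0.25 Hz resolution, and summed over the
#' spectral bins falling inside each band (delta 1-4, sigma 12-15, beta
#' 18-25 Hz by default; the beta lower edge in particular is
#' subject-configurable). The window is power-corrected so that the summed
#' spectrum matches the signal's mean square (Parseval). Epochs overlapping
#' an artefact-masked second are returned as missing so that time continuity
#' is preserved.
#'
#' @param record An \linkS4class{EEGRecord}; the sampling rate must put the
#'   highest band edge below Nyquist.
#' @param bands Named list of \code{c(low, high)} band edges in Hz.
#' @param epochSec Epoch length in seconds (default 4).
#' @param valid Optional logical vector, one flag per second, from
#'   [artefactMask()]; FALSE seconds poison the epochs containing them.
#' @return A data.frame with columns \code{time} (epoch start, s),
#'   \code{delta}, \code{sigma}, \code{beta} (uV^2; NA for masked epochs).
#' @export
epochBandPower <- function(record, bands = DEFAULT_BANDS, epochSec = 4,
                           valid = NULL) {
  stopifnot(is(record, "EEGRecord"))
  fs <- record@rate
  hi <- max(vapply(bands, max, numeric(1)))
  if (fs / 2 < hi)
    stop("sampling rate too low: Nyquist below the highest band edge")
  n <- as.integer(round(fs * epochSec))
  if (length(record@samples) < n) stop("record shorter than one epoch")
  nEpoch <- length(record@samples) %/% n
  w <- 0.5 * (1 - cos(2 * pi * seq(0, n - 1) / n))  # Hann
  u <- sum(w^2)                                      # window power correction
  freqs <- seq(0, fs / 2, by = fs / n)
  bandBins <- lapply(bands, function(b)
    which(freqs >= b[1] & freqs <= b[2] & freqs > 0))
  out <- matrix(NA_real_, nEpoch, length(bands),
                dimnames = list(NULL, names(bands)))
  for (e in seq_len(nEpoch)) {
    i0 <- (e - 1L) * n
    if (!is.null(valid)) {
      secs <- floor(i0 / fs) + seq_len(ceiling(epochSec))
      secs <- secs[secs <= length(valid)]
      if (any(!valid[secs])) next
    }
    x <- record@samples[i0 + seq_len(n)]
    X <- stats::fft(x * w)
    nyq <- n %/% 2 + 1L
    pw <- Mod(X[seq_len(nyq)])^2 / (n * u)  # Parseval: one-sided sum = mean square
    pw[2:(nyq - 1L)] <- 2 * pw[2:(nyq - 1L)]        # one-sided
    out[e, ] <- vapply(bandBins, function(idx) sum(pw[idx]), numeric(1))
  }
  data.frame(time = (seq_len(nEpoch) - 1L) * epochSec, out)
}

#' RMS-based artefact mask at 1-s resolution
#'
#' Computes the root-mean-square amplitude of each 1-s segment and compares
#' it with a background level given by a rolling median of the per-second
#' RMS (3-minute window by default). Seconds whose RMS exceeds \code{k}
#' times the background are flagged invalid; downstream they become missing
#' data rather than being cut out, preserving time continuity. The window
#' and threshold are this package's documented constants for the
#' background-dependent principle.
#'
#' @param record An \linkS4class{EEGRecord}.
#' @param k Threshold multiple of the background RMS (default 4).
#' @param windowSec Background window in seconds (default 180).
#' @return Logical vector, one element per whole second; TRUE = valid.
#' @export
artefactMask <- function(record, k = 4, windowSec = 180) {
  stopifnot(is(record, "EEGRecord"))
  fs <- record@rate
  nSec <- length(record@samples) %/% fs
  if (nSec < 3L) stop("record shorter than the minimum background window")
  rms <- vapply(seq_len(nSec), function(s) {
    x <- record@samples[(s - 1L) * fs + seq_len(fs)]
    sqrt(mean(x^2))
  }, numeric(1))
  wl <- min(2L * (windowSec %/% 2L) + 1L, 2L * ((nSec - 1L) %/% 2L) + 1L)
  bg <- zoo::rollmedian(rms, wl, fill = NA, align = "center")
  # pad the edges with the nearest computed background
  bg <- zoo::na.locf(zoo::na.locf(bg, na.rm = FALSE), fromLast = TRUE)
  rms <= k * bg
}

.isSleep <- function(stage) stage %in% c("S1", "S2", "S3", "S4", "REM")

#' Segment a hypnogram into NREM episodes
#'
#' REM episodes are delimited with the 15-minute combining rule: successive
#' REM bouts separated by less than 15 min of non-REM belong to one REM
#' episode, which ends at its last REM epoch once 15 min elapse without REM.
#' A single REM epoch suffices to start a REM episode. The first NREM
#' episode starts at sleep onset (first stage-2 epoch); each later NREM
#' episode starts at the epoch immediately following the previous REM
#' episode's end and runs to the epoch before the next REM episode (or the
#' last sleep epoch for the final episode, so trailing wake is ignored).
#'
#' @param hyp A \linkS4class{Hypnogram}.
#' @param maxEpisodes Number of NREM episodes to return (default 4).
#' @return A data.frame with columns \code{nrem}, \code{startEpoch},
#'   \code{endEpoch} (1-based, inclusive). Fewer than \code{maxEpisodes}
#'   rows are returned with a warning when the night does not contain them.
#' @export
segmentEpisodes <- function(hyp, maxEpisodes = 4L) {
  stopifnot(is(hyp, "Hypnogram"))
  st <- hyp@stages
  onset <- match("S2", st)
  if (is.na(onset)) stop("no stage-2 sleep: cannot set sleep onset")
  gap <- 45L  # 15 min of 20-s epochs
  remIdx <- which(st == "REM" & seq_along(st) >= onset)
  remEp <- list()
  if (length(remIdx)) {
    brk <- which(diff(remIdx) > gap)
    starts <- remIdx[c(1L, brk + 1L)]
    ends <- remIdx[c(brk, length(remIdx))]
    remEp <- Map(c, starts, ends)
  }
  lastSleep <- max(which(.isSleep(st)))
  nremStart <- onset
  out <- list()
  for (i in seq_len(length(remEp) + 1L)) {
    nremEnd <- if (i <= length(remEp)) remEp[[i]][1] - 1L else lastSleep
    if (nremEnd >= nremStart)
      out[[length(out) + 1L]] <- c(start = nremStart, end = nremEnd)
    if (i <= length(remEp)) nremStart <- remEp[[i]][2] + 1L
    if (length(out) >= maxEpisodes) break
  }
  if (length(out) < maxEpisodes)
    warning(sprintf("only %d NREM episode(s) found", length(out)))
  data.frame(nrem = seq_along(out),
             startEpoch = vapply(out, `[[`, integer(1), "start"),
             endEpoch = vapply(out, `[[`, integer(1), "end"))
}

#' Sleep latency and efficiency from a hypnogram
#'
#' Latency is the interval between lights-off and the first occurrence of
#' stage 2 sleep, in minutes. The sleep efficiency index is the ratio of
#' total sleep time (excluding waking intervals) to the total sleep period
#' (including waking intervals), the period running from sleep onset to the
#' last sleep epoch.
#'
#' @param hyp A \linkS4class{Hypnogram}.
#' @return A list with \code{latencyMin} and \code{efficiency}.
#' @export
sleepStatistics <- function(hyp) {
  stopifnot(is(hyp, "Hypnogram"))
  st <- hyp@stages
  onset <- match("S2", st)
  if (is.na(onset)) stop("no stage-2 sleep: latency undefined")
  latency <- (onset - hyp@lightsOff) * (20 / 60)
  span <- onset:max(which(.isSleep(st)))
  list(latencyMin = latency,
       efficiency = sum(.isSleep(st[span])) / length(span))
}

#' Episode band-power time courses from EEG and hypnogram
#'
#' Composes [artefactMask()], [epochBandPower()], [segmentEpisodes()] and
#' [rebinNormalize()]: every NREM episode found is reduced to the 50-bin
#' normalised \linkS4class{PowerTimeCourse} the fitting stage consumes.
#'
#' @param record An \linkS4class{EEGRecord} starting at epoch 1 of the
#'   hypnogram.
#' @param hyp A \linkS4class{Hypnogram}.
#' @param bands Band edges passed to [epochBandPower()].
#' @param mask Apply artefact masking (default TRUE).
#' @return A list of \linkS4class{PowerTimeCourse}, one per NREM episode.
#' @export
episodePowerCourses <- function(record, hyp, bands = DEFAULT_BANDS,
                                mask = TRUE) {
  valid <- if (mask) artefactMask(record) else NULL
  pw <- epochBandPower(record, bands = bands, valid = valid)
  seg <- segmentEpisodes(hyp)
  lapply(seq_len(nrow(seg)), function(i) {
    t0 <- (seg$startEpoch[i] - 1L) * 20
    t1 <- seg$endEpoch[i] * 20
    sel <- pw$time >= t0 & pw$time < t1
    rebinNormalize(pw[sel, ], bounds = c(t0, t1))
  })
}
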