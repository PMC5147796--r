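#' @include AllClasses.R utils.R
NULL

#' Zero-phase band-pass filter
#'
#' Applies a Butterworth band-pass (order 2, run forward and backward with
#' `signal::filtfilt`, i.e. an effective 4th-order zero-phase response) to
#' every channel. Phase neutrality matters for event timing: the extremum of
#' an embedded deflection must not shift.
#'
#' @param ts a [TimeSeriesRecording-class].
#' @param lowHz,highHz band edges; `0 < lowHz < highHz < samplingRate/2`.
#' @param order Butterworth order per pass (default 2).
#' @return A filtered [TimeSeriesRecording-class].
#' @export
bandpassFilter <- function(ts, lowHz, highHz, order = 2) {
  stopifnot(is(ts, "TimeSeriesRecording"))
  nyq <- samplingRate(ts) / 2
  if (!(lowHz > 0 && lowHz < highHz && highHz < nyq)) {
    stop(sprintf("invalid band [%g, %g] Hz for Nyquist %g Hz", lowHz, highHz, nyq),
         call. = FALSE)
  }
  bf <- signal::butter(order, c(lowHz, highHz) / nyq, type = "pass")
  mat <- samples(ts)
  out <- t(apply(mat, 1L, function(x) signal::filtfilt(bf, x)))
  TimeSeriesRecording(out, samplingRate = samplingRate(ts),
                      channelIds = channelIds(ts), t0 = ts@t0)
}

#' Per-channel signal SD
#'
#' Estimates the detection-threshold SD for each channel either from a short
#' baseline window (slice preparations, where quiescent epochs exist) or
#' from the entire signal (awake recordings). Constant channels are flagged
#' NA and must be skipped downstream.
#'
#' @param ts a [TimeSeriesRecording-class].
#' @param mode "baseline_window" or "full_signal".
#' @param windowS baseline window length (s), used in baseline_window mode.
#' @param windowStartS start of the baseline window (s from recording start).
#' @return Named numeric vector of SDs (uV); NA for constant channels, with
#'   the excluded channel indices in `attr(, "excluded")`.
#' @export
estimateChannelSD <- function(ts, mode = c("full_signal", "baseline_window"),
                              windowS = 2, windowStartS = 0) {
  stopifnot(is(ts, "TimeSeriesRecording"))
  mode <- match.arg(mode)
  mat <- samples(ts)
  if (mode == "baseline_window") {
    fs <- samplingRate(ts)
    i0 <- floor(windowStartS * fs) + 1L
    i1 <- min(ncol(mat), i0 + ceiling(windowS * fs) - 1L)
    if (i0 < 1L || i0 >= i1 || i1 > ncol(mat)) {
      stop("baseline window outside the recording", call. = FALSE)
    }
    mat <- mat[, i0:i1, drop = FALSE]
  }
  sds <- apply(mat, 1L, sd)
  const <- !is.finite(sds) | sds < 1e-12
  sds[const] <- NA_real_
  names(sds) <- channelIds(ts)
  attr(sds, "excluded") <- which(unname(const))
  sds
}

# One event per contiguous supra-threshold excursion, at the signed extremum.
excursionEvents <- function(x, thr, negative = TRUE) {
  below <- if (negative) x < thr else x > thr
  if (!any(below)) return(integer(0))
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  starts <- starts[r$values]; ends <- ends[r$values]
  vapply(seq_along(starts), function(i) {
    seg <- starts[i]:ends[i]
    seg[if (negative) which.min(x[seg]) else which.max(x[seg])]
  }, integer(1))
}

#' Detect LFP deflection events (nLFP / pLFP)
#'
#' For each contiguous excursion of the signal beyond `z * SD` exactly one
#' event is emitted at the signed extremum (the minimum of the excursion for
#' negative polarity), carrying its amplitude in uV and its time. Typical
#' thresholds: z = -2.5 (awake nLFP), z = -4.5 (slice nLFP), z = +2.5 to +3
#' (striatal pLFP).
#'
#' @param ts a (band-pass filtered) [TimeSeriesRecording-class].
#' @param z threshold in SD units; sign selects nothing by itself - use
#'   `polarity` - but must be non-zero.
#' @param polarity "negative" or "positive".
#' @param sds optional per-channel SD vector (from [estimateChannelSD()]);
#'   computed with full_signal mode when missing. Channels with NA SD are
#'   skipped with a warning.
#' @return An [EventRaster-class].
#' @export
detectLfpEvents <- function(ts, z, polarity = c("negative", "positive"),
                            sds = NULL) {
  stopifnot(is(ts, "TimeSeriesRecording"))
  polarity <- match.arg(polarity)
  if (z == 0) stop("'z' must be non-zero", call. = FALSE)
  z <- abs(z)
  if (is.null(sds)) sds <- estimateChannelSD(ts, "full_signal")
  mat <- samples(ts)
  fs <- samplingRate(ts)
  if (any(is.na(sds))) {
    warning(sprintf("skipping %d constant channel(s)", sum(is.na(sds))))
  }
  times <- numeric(0); chans <- integer(0); amps <- numeric(0)
  for (ch in seq_len(nrow(mat))) {
    if (is.na(sds[ch])) next
    neg <- polarity == "negative"
    thr <- if (neg) -z * sds[ch] else z * sds[ch]
    idx <- excursionEvents(mat[ch, ], thr, negative = neg)
    if (!length(idx)) next
    times <- c(times, ts@t0 + (idx - 1L) / fs)
    chans <- c(chans, rep.int(ch, length(idx)))
    amps <- c(amps, mat[ch, idx])
  }
  EventRaster(times - ts@t0, chans, amps,
              duration = ncol(mat) / fs, nChannels = nrow(mat))
}

#' Detect multi-unit activity (MUA) spikes
#'
#' Negative threshold crossings on a high-pass/band-pass filtered signal
#' (300-4000 Hz band in slices; > 250 Hz awake) emit one spike each, with a
#' refractory dead-time merge window. Threshold rule: `k * SD` per channel
#' (slices, k = -5) or `k * RMS` (awake, k = -6); for zero-mean signals the
#' two coincide.
#'
#' @param ts a filtered [TimeSeriesRecording-class].
#' @param rule "sd" or "rms".
#' @param k threshold multiplier (< 0).
#' @param deadTimeMs refractory merge window (ms, default 1).
#' @return An [EventRaster-class] of spike times (amplitude = excursion
#'   minimum, uV).
#' @export
detectMuaEvents <- function(ts, rule = c("sd", "rms"), k = -5, deadTimeMs = 1) {
  stopifnot(is(ts, "TimeSeriesRecording"))
  rule <- match.arg(rule)
  if (k >= 0) stop("'k' must be negative", call. = FALSE)
  mat <- samples(ts)
  fs <- samplingRate(ts)
  deadSamp <- max(1L, round(deadTimeMs / 1000 * fs))
  times <- numeric(0); chans <- integer(0); amps <- numeric(0)
  for (ch in seq_len(nrow(mat))) {
    x <- mat[ch, ]
    scale <- if (rule == "sd") sd(x) else sqrt(mean(x^2))
    if (!is.finite(scale) || scale < 1e-12) {
      warning(sprintf("skipping constant channel %d", ch))
      next
    }
    thr <- k * scale
    below <- x < thr
    onsets <- which(below & !c(FALSE, below[-length(below)]))
    if (!length(onsets)) next
    keep <- c(TRUE, diff(onsets) > deadSamp)
    # enforce dead time sequentially (a kept onset resets the window)
    last <- onsets[1L]
    for (i in seq_along(onsets)[-1L]) {
      keep[i] <- (onsets[i] - last) > deadSamp
      if (keep[i]) last <- onsets[i]
    }
    onsets <- onsets[keep]
    amp <- vapply(onsets, function(o) {
      min(x[o:min(length(x), o + deadSamp)])
    }, numeric(1))
    times <- c(times, (onsets - 1L) / fs)
    chans <- c(chans, rep.int(ch, length(onsets)))
    amps <- c(amps, amp)
  }
  EventRaster(times, chans, amps, duration = ncol(mat) / fs,
              nChannels = nrow(mat))
}

#' Event-triggered average with a shuffle band
#'
#' Averages signal snippets around trigger times and derives a +/- 3 SD
#' confidence band from averages recomputed with the same number of triggers
#' placed uniformly at random (the shuffle null for locked structure).
#' Triggers whose window would cross a recording edge are excluded.
#'
#' @param ts a [TimeSeriesRecording-class].
#' @param triggerTimes trigger times (s, relative to recording start).
#' @param windowS half-window (s); snippets span +/- windowS.
#' @param nShuffles number of shuffle repetitions (default 100).
#' @param channel channel index to average, or NULL to average across all
#'   channels.
#' @param seed RNG seed for the shuffles.
#' @return list with `lagS`, `average`, `bandLo`, `bandHi`, `nTriggers`.
#' @export
triggeredAverage <- function(ts, triggerTimes, windowS = 0.1, nShuffles = 100,
                             channel = NULL, seed = 1) {
  stopifnot(is(ts, "TimeSeriesRecording"))
  mat <- samples(ts)
  fs <- samplingRate(ts)
  halfW <- round(windowS * fs)
  n <- ncol(mat)
  rows <- if (is.null(channel)) seq_len(nrow(mat)) else channel
  snippetMean <- function(tt) {
    centres <- round(tt * fs) + 1L
    ok <- centres - halfW >= 1L & centres + halfW <= n
    centres <- centres[ok]
    if (!length(centres)) return(NULL)
    acc <- numeric(2L * halfW + 1L)
    for (cn in centres) {
      seg <- mat[rows, (cn - halfW):(cn + halfW), drop = FALSE]
      acc <- acc + Matrix::colSums(seg) / length(rows)
    }
    acc / length(centres)
  }
  avg <- snippetMean(triggerTimes)
  if (is.null(avg)) stop("no trigger with a complete window", call. = FALSE)
  nUse <- sum(round(triggerTimes * fs) + 1L - halfW >= 1L &
              round(triggerTimes * fs) + 1L + halfW <= n)
  shuf <- withSeed(seed, {
    vapply(seq_len(nShuffles), function(i) {
      tt <- runif(nUse, windowS, n / fs - windowS)
      snippetMean(tt)
    }, numeric(2L * halfW + 1L))
  })
  mu <- rowMeans(shuf)
  sdv <- apply(shuf, 1L, sd)
  list(lagS = seq(-halfW, halfW) / fs,
       average = avg,
       bandLo = mu - 3 * sdv,
       bandHi = mu + 3 * sdv,
       nTriggers = nUse)
}

#' Normalized event-locked power spectral density
#'
#' Hann-windowed periodograms of snippets around event times (default
#' +/- 0.5 s), averaged over events and channels, then normalized so the
#' integral over frequency equals one.
#'
#' @param ts a [TimeSeriesRecording-class].
#' @param eventTimes event times (s).
#' @param windowS half-window (s, default 0.5).
#' @return data.frame with `freqHz` and `density` (integrates to 1).
#' @export
normalizedPsd <- function(ts, eventTimes, windowS = 0.5) {
  stopifnot(is(ts, "TimeSeriesRecording"))
  mat <- samples(ts)
  fs <- samplingRate(ts)
  halfW <- round(windowS * fs)
  L <- 2L * halfW
  n <- ncol(mat)
  centres <- round(eventTimes * fs) + 1L
  centres <- centres[centres - halfW >= 1L & centres + halfW - 1L <= n]
  if (!length(centres)) stop("no event with a complete window", call. = FALSE)
  hann <- 0.5 * (1 - cos(2 * pi * seq(0, L - 1) / (L - 1)))
  nFreq <- L %/% 2L + 1L
  acc <- numeric(nFreq)
  for (cn in centres) {
    for (ch in seq_len(nrow(mat))) {
      x <- mat[ch, (cn - halfW):(cn + halfW - 1L)] * hann
      P <- abs(fft(x))^2
      acc <- acc + P[seq_len(nFreq)]
    }
  }
  freq <- seq(0, nFreq - 1L) * fs / L
  df <- fs / L
  dens <- acc / (sum(acc) * df)
  data.frame(freqHz = freq, density = dens)
}
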