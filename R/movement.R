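#' @include AllClasses.R utils.R
NULL

#' Movement signal from a frame stream
#'
#' Computes 1 minus the Pearson correlation between consecutive ROI pixel
#' vectors of a grayscale frame stack: 0 for identical frames, up to 2 for
#' anticorrelated ones. Constant frames (undefined correlation) yield 0 and
#' are flagged. A precomputed numeric series can be wrapped directly.
#'
#' @param frames either a 3D array (height x width x frames), a list of
#'   matrices, or a precomputed numeric series.
#' @param fps frames per second.
#' @param roi optional index matrix/logical mask selecting the ROI pixels
#'   (applied to each frame); NULL uses the full frame.
#' @param roiLabel label stored in the result.
#' @return A [MovementSignal-class] of length frames - 1 (or the series
#'   length); flagged transitions in `attr(, "flaggedFrames")`.
#' @export
movementSignal <- function(frames, fps, roi = NULL, roiLabel = "roi") {
  assertScalar(fps, "fps", lower = 0, strictLower = TRUE)
  if (is.numeric(frames) && is.null(dim(frames))) {
    return(new("MovementSignal", values = as.numeric(frames), fps = fps,
               roi = roiLabel))
  }
  asList <- if (is.array(frames) && length(dim(frames)) == 3L) {
    lapply(seq_len(dim(frames)[3]), function(k) frames[, , k])
  } else if (is.list(frames)) {
    frames
  } else {
    stop("frames must be a 3D array, a list of matrices, or a numeric series",
         call. = FALSE)
  }
  if (length(asList) < 2L) stop("need >= 2 frames", call. = FALSE)
  pix <- function(f) {
    v <- if (is.null(roi)) as.numeric(f) else as.numeric(f[roi])
    v
  }
  vals <- numeric(length(asList) - 1L)
  flagged <- integer(0)
  prev <- pix(asList[[1L]])
  for (k in 2:length(asList)) {
    cur <- pix(asList[[k]])
    if (sd(prev) < 1e-14 || sd(cur) < 1e-14) {
      vals[k - 1L] <- 0
      flagged <- c(flagged, k - 1L)
    } else {
      vals[k - 1L] <- 1 - cor(prev, cur)
    }
    prev <- cur
  }
  out <- new("MovementSignal", values = vals, fps = fps, roi = roiLabel)
  if (length(flagged)) attr(out, "flaggedFrames") <- flagged
  out
}

#' Detect involuntary movements
#'
#' Thresholds the movement signal at `mean + z * SD` (z = 2-3 typical); each
#' supra-threshold excursion yields one event with onset at its first
#' supra-threshold frame. Also returns the event rate and the inter-event
#' interval distribution as a normalised PDF. An optional resting mask
#' restricts both the SD estimate and the detection to resting periods.
#'
#' @param ms a [MovementSignal-class] of at least `minDurationS` seconds.
#' @param z threshold in SD units (> 0).
#' @param restingMask optional logical vector (TRUE = resting) of the signal
#'   length.
#' @param minDurationS minimum signal length (s, default 10).
#' @return list with `events` (data.frame: time, peak, durationFrames),
#'   `rate` (s^-1), `intervalPdf` (data.frame: mid, density) and
#'   `threshold`.
#' @export
detectMovements <- function(ms, z = 2.5, restingMask = NULL, minDurationS = 10) {
  stopifnot(is(ms, "MovementSignal"))
  assertScalar(z, "z", lower = 0, strictLower = TRUE)
  v <- ms@values
  if (length(v) / ms@fps < minDurationS) {
    stop(sprintf("signal shorter than %g s", minDurationS), call. = FALSE)
  }
  use <- if (is.null(restingMask)) rep(TRUE, length(v)) else restingMask
  mu <- mean(v[use]); sdv <- sd(v[use])
  if (!is.finite(sdv) || sdv < 1e-14) stop("zero SD movement signal", call. = FALSE)
  thr <- mu + z * sdv
  above <- v > thr & use
  if (!any(above)) {
    return(list(events = data.frame(time = numeric(0), peak = numeric(0),
                                    durationFrames = integer(0)),
                rate = 0, intervalPdf = NULL, threshold = thr))
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  starts <- starts[r$values]; ends <- ends[r$values]
  evs <- data.frame(
    time = (starts - 1L) / ms@fps,
    peak = vapply(seq_along(starts), function(i) max(v[starts[i]:ends[i]]),
                  numeric(1)),
    durationFrames = as.integer(ends - starts + 1L)
  )
  rate <- nrow(evs) / (length(v) / ms@fps)
  intervalPdf <- NULL
  if (nrow(evs) >= 3) {
    iv <- diff(evs$time)
    h <- hist(iv, breaks = "FD", plot = FALSE)
    intervalPdf <- data.frame(mid = h$mids, density = h$density)
  }
  list(events = evs, rate = rate, intervalPdf = intervalPdf, threshold = thr)
}

#' Movement-triggered LFP average
#'
#' Delegates to [triggeredAverage()] with movement onsets as triggers:
#' the average LFP waveform around involuntary movements, with the shuffle
#' band as the null for movement-locked structure.
#'
#' @param ts a [TimeSeriesRecording-class].
#' @param movementTimes movement onset times (s).
#' @param windowS half-window (s).
#' @param ... further arguments for [triggeredAverage()].
#' @return See [triggeredAverage()].
#' @export
movementTriggeredLfp <- function(ts, movementTimes, windowS = 0.5, ...) {
  triggeredAverage(ts, movementTimes, windowS = windowS, ...)
}
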