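#' @include AllClasses.R utils.R
NULL

#' Compute dF/F in percent
#'
#' `dF/F = 100 * (F_ROI - F_0) / F_0`, where both the ROI fluorescence and
#' the baseline are background-corrected (the dark-background signal is
#' subtracted from the raw ROI trace first). Frames with a non-positive
#' baseline are flagged invalid (NA).
#'
#' @param fRoi raw ROI fluorescence trace.
#' @param baseline baseline F_0 per frame (or scalar), already
#'   background-corrected.
#' @param fBackground background trace (or scalar) subtracted from `fRoi`;
#'   default 0 for pre-corrected input.
#' @return dF/F trace in percent; invalid frames NA with their indices in
#'   `attr(, "invalidFrames")`.
#' @examples
#' computeDFF(110, 100)                       # 10
#' computeDFF(130, 100, fBackground = 20)     # 10
#' @export
computeDFF <- function(fRoi, baseline, fBackground = 0) {
  f <- fRoi - fBackground
  bad <- !(baseline > 0)
  dff <- 100 * (f - baseline) / baseline
  dff[bad] <- NA_real_
  if (any(bad)) attr(dff, "invalidFrames") <- which(bad)
  dff
}

#' Sliding lower-half baseline
#'
#' Per-frame baseline estimated from a centred sliding window (default 30 s)
#' as the mean of the 50% smallest values in the window, which excludes the
#' transients that correspond to neuronal activity. Windows are truncated at
#' the trace edges.
#'
#' @param trace fluorescence (or dF/F) trace.
#' @param frameRate frames per second.
#' @param windowS window length (s, default 30); must not exceed the trace.
#' @return Baseline trace of the same length.
#' @export
rollingBaseline <- function(trace, frameRate, windowS = 30) {
  assertScalar(frameRate, "frameRate", lower = 0, strictLower = TRUE)
  n <- length(trace)
  w <- round(windowS * frameRate)
  if (w > n) stop("window longer than the trace", call. = FALSE)
  half <- w %/% 2L
  vapply(seq_len(n), function(i) {
    lowerHalfMean(trace[max(1L, i - half):min(n, i + half)])
  }, numeric(1))
}

#' Detect calcium transients on the summated-increment signal
#'
#' Successive positive frame-to-frame increases of dF/F are summated; the
#' running sum resets whenever an increment is non-positive. A transient is
#' emitted when the summated signal crosses `threshold` during a rising
#' epoch - one peak per epoch, at the epoch's local maximum, with amplitude
#' equal to dF/F at that maximum. Summating increments makes slow multi-frame
#' rises detectable while single-frame noise excursions rarely accumulate
#' enough, keeping the spurious-peak fraction below half a percent of frames.
#'
#' @param dff dF/F trace (%), baseline-corrected or raw (the increments are
#'   insensitive to slow drift over a few frames).
#' @param threshold detection threshold on the summated signal (dF/F %);
#'   default `thresholdSdFactor` times a robust noise SD estimated from the
#'   frame-to-frame increments (`mad(diff(dff))/sqrt(2)`).
#' @param thresholdSdFactor multiplier for the default threshold (default 5).
#' @return data.frame with `frame`, `amplitude` (dF/F % at the epoch
#'   maximum) and `summated` (summated signal at the maximum); the threshold
#'   used is in `attr(, "threshold")`.
#' @export
detectCaPeaks <- function(dff, threshold = NULL, thresholdSdFactor = 5) {
  dff <- as.numeric(dff)
  n <- length(dff)
  if (is.null(threshold)) {
    noiseSd <- mad(diff(dff), na.rm = TRUE) / sqrt(2)
    threshold <- thresholdSdFactor * noiseSd
  }
  frames <- integer(0); amps <- numeric(0); sums <- numeric(0)
  s <- 0; armed <- FALSE
  if (n >= 2) {
    for (i in 2:n) {
      inc <- dff[i] - dff[i - 1L]
      if (is.na(inc)) { s <- 0; armed <- FALSE; next }
      if (inc > 0) {
        s <- s + inc
        if (!armed && s > threshold) armed <- TRUE
      } else {
        if (armed) {   # rising epoch ended at i-1: that frame is the peak
          frames <- c(frames, i - 1L)
          amps <- c(amps, dff[i - 1L])
          sums <- c(sums, s)
        }
        s <- 0; armed <- FALSE
      }
    }
    if (armed) {
      frames <- c(frames, n); amps <- c(amps, dff[n]); sums <- c(sums, s)
    }
  }
  out <- data.frame(frame = frames, amplitude = amps, summated = sums)
  attr(out, "threshold") <- threshold
  out
}

#' Spike-count versus dF/F amplitude regression
#'
#' Per neuron, transient amplitudes are averaged within each spike-count
#' level and normalised so that the neuron's 2-spike mean equals unity (the
#' anchor level; neurons without 2-spike events are excluded and flagged).
#' A pooled ordinary least-squares regression of normalised amplitude on
#' spike count is returned - a linear relation with high R^2 validates dF/F
#' amplitude as a spike-count proxy.
#'
#' @param spikeCounts integer spike counts per event.
#' @param peakAmps dF/F amplitudes per event (%).
#' @param neuronIds neuron label per event.
#' @return list with `slope`, `intercept`, `r2`, `table` (neuron x count
#'   normalised means) and `excludedNeurons`.
#' @export
spikeDffRegression <- function(spikeCounts, peakAmps, neuronIds) {
  stopifnot(length(spikeCounts) == length(peakAmps),
            length(peakAmps) == length(neuronIds))
  if (length(unique(spikeCounts)) < 3) {
    stop("need >= 3 distinct spike-count levels", call. = FALSE)
  }
  df <- data.frame(n = neuronIds, k = spikeCounts, a = peakAmps)
  agg <- aggregate(a ~ n + k, data = df, FUN = mean)
  excluded <- character(0)
  rows <- list()
  for (neuron in unique(agg$n)) {
    sub <- agg[agg$n == neuron, ]
    anchor <- sub$a[sub$k == 2]
    if (!length(anchor)) {
      excluded <- c(excluded, as.character(neuron))
      next
    }
    sub$norm <- sub$a / anchor
    rows[[length(rows) + 1L]] <- sub
  }
  if (!length(rows)) stop("no neuron with 2-spike events", call. = FALSE)
  pooled <- do.call(rbind, rows)
  fit <- lm(norm ~ k, data = pooled)
  list(slope = unname(coef(fit)[2]),
       intercept = unname(coef(fit)[1]),
       r2 = cor(pooled$norm, pooled$k)^2,  # R^2 of the simple regression
       table = pooled[, c("n", "k", "norm")],
       excludedNeurons = excluded)
}

#' Population-episode rate from the bulk fluorescence signal
#'
#' Detects transients on the summed (bulk) fluorescence trace with
#' [detectCaPeaks()] and reports their rate. Because population episodes are
#' correlated across neurons, the bulk rate approximates the cortical input
#' rate arriving at the striatal population.
#'
#' @param bulk bulk dF/F trace (%), e.g. `colSums(traces(cts))` after
#'   baseline removal, or any summed widefield signal.
#' @param frameRate frames per second.
#' @param threshold passed to [detectCaPeaks()].
#' @return list with `rate` (s^-1), `nEpisodes`, `peaks`.
#' @export
episodeRate <- function(bulk, frameRate, threshold = NULL) {
  assertScalar(frameRate, "frameRate", lower = 0, strictLower = TRUE)
  peaks <- detectCaPeaks(bulk, threshold = threshold)
  durationS <- length(bulk) / frameRate
  list(rate = nrow(peaks) / durationS, nEpisodes = nrow(peaks), peaks = peaks)
}

#' Functional-connectivity stability across time segments
#'
#' Splits the recording into consecutive segments (default ~120 s), computes
#' the vector of pairwise zero-lag CCs on the dF/F traces within each
#' segment, and regresses each segment's CC vector on the previous one by
#' ordinary least squares. The resulting R^2 per consecutive pair measures
#' how stable the functional-connectivity pattern is: near 1 for a frozen
#' network, near 0 when the coupling structure reorganises. The same
#' machinery applies to per-neuron mean transient amplitudes via
#' `statistic = "amplitude"`.
#'
#' @param cts a [CalciumTraceSet-class] (>= 2 neurons, >= 2 full segments).
#' @param segmentS segment length (s, default 120).
#' @param statistic "cc" (pairwise CC vectors) or "amplitude" (per-neuron
#'   mean transient amplitude per segment).
#' @return A [SegmentStability-class].
#' @export
segmentStabilityR2 <- function(cts, segmentS = 120, statistic = c("cc", "amplitude")) {
  stopifnot(is(cts, "CalciumTraceSet"))
  statistic <- match.arg(statistic)
  tr <- traces(cts)
  if (nrow(tr) < 2) stop("need >= 2 neurons", call. = FALSE)
  segFrames <- floor(segmentS * frameRate(cts))
  nSeg <- floor(ncol(tr) / segFrames)
  if (nSeg < 2) stop("need >= 2 full segments", call. = FALSE)
  vecs <- vapply(seq_len(nSeg), function(sgi) {
    idx <- ((sgi - 1L) * segFrames + 1L):(sgi * segFrames)
    seg <- tr[, idx, drop = FALSE]
    if (statistic == "cc") {
      ok <- apply(seg, 1L, sd) > 1e-14
      cm <- matrix(NA_real_, nrow(tr), nrow(tr))
      if (sum(ok) >= 2) cm[ok, ok] <- cor(t(seg[ok, , drop = FALSE]))
      cm[upper.tri(cm)]
    } else {
      vapply(seq_len(nrow(seg)), function(i) {
        pk <- detectCaPeaks(seg[i, ])
        if (nrow(pk)) mean(pk$amplitude) else NA_real_
      }, numeric(1))
    }
  }, numeric(if (statistic == "cc") nrow(tr) * (nrow(tr) - 1L) / 2L else nrow(tr)))
  vecs <- as.matrix(vecs)
  r2 <- vapply(seq_len(nSeg - 1L), function(sgi) {
    a <- vecs[, sgi]; b <- vecs[, sgi + 1L]
    ok <- is.finite(a) & is.finite(b)
    if (sum(ok) < 3) return(NA_real_)
    if (sd(a[ok]) < 1e-14 || sd(b[ok]) < 1e-14) return(NA_real_)
    cor(a[ok], b[ok])^2  # R^2 of the OLS of later on earlier CCs
  }, numeric(1))
  new("SegmentStability", ccVectors = vecs, r2 = r2, segmentLengthS = segmentS)
}
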