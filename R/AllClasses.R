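#' @include utils.R
NULL

#' Multichannel continuous recording
#'
#' Container for a channels-by-time matrix of extracellular signal (uV) with a
#' common sampling rate. All analysis entry points that consume continuous
#' signal (filtering, event detection, triggered averages, spectra) operate on
#' this class.
#'
#' @slot samples numeric matrix, channels x time, in microvolts.
#' @slot samplingRate sampling rate in Hz.
#' @slot channelIds character vector of channel labels.
#' @slot t0 start time of the first sample in seconds.
#' @export
setClass("TimeSeriesRecording",
  representation(samples = "matrix", samplingRate = "numeric",
                 channelIds = "character", t0 = "numeric"),
  prototype(t0 = 0),
  validity = function(object) {
    msg <- character(0)
    if (length(object@samplingRate) != 1L || object@samplingRate <= 0) {
      msg <- c(msg, "samplingRate must be a positive scalar")
    }
    if (nrow(object@samples) != length(object@channelIds)) {
      msg <- c(msg, "one channelId per row of samples required")
    }
    if (length(object@t0) != 1L || !is.finite(object@t0)) {
      msg <- c(msg, "t0 must be a finite scalar")
    }
    if (length(msg)) msg else TRUE
  })

#' Construct a TimeSeriesRecording
#'
#' @param samples channels x time numeric matrix (uV).
#' @param samplingRate sampling rate (Hz).
#' @param channelIds optional channel labels; defaults to ch1..chK.
#' @param t0 start time (s).
#' @return A [TimeSeriesRecording-class] object.
#' @examples
#' ts <- TimeSeriesRecording(matrix(rnorm(2000), nrow = 2), samplingRate = 1000)
#' ts
#' @export
TimeSeriesRecording <- function(samples, samplingRate, channelIds = NULL, t0 = 0) {
  samples <- as.matrix(samples)
  if (is.null(channelIds)) channelIds <- paste0("ch", seq_len(nrow(samples)))
  new("TimeSeriesRecording", samples = samples, samplingRate = samplingRate,
      channelIds = as.character(channelIds), t0 = t0)
}

#' Timestamped extracellular events on a multichannel array
#'
#' Events (nLFP/pLFP deflection extrema or MUA spikes) as a table of
#' (time, channel, amplitude), sorted by time. The substrate for avalanche
#' binning and correlation analysis. Amplitudes are signed extrema in uV and
#' may be NA for discrete-only (spike) rasters.
#'
#' @slot events data.frame with columns time (s), channel (integer index),
#'   amplitude (uV, signed, possibly NA).
#' @slot duration recording duration in seconds.
#' @slot nChannels number of channels on the array.
#' @export
setClass("EventRaster",
  representation(events = "data.frame", duration = "numeric",
                 nChannels = "integer"),
  validity = function(object) {
    ev <- object@events
    msg <- character(0)
    need <- c("time", "channel", "amplitude")
    if (!all(need %in% names(ev))) {
      msg <- c(msg, "events must have columns time, channel, amplitude")
    } else {
      if (nrow(ev) && is.unsorted(ev$time)) msg <- c(msg, "events must be sorted by time")
      if (nrow(ev) && (min(ev$time) < 0 || max(ev$time) > object@duration)) {
        msg <- c(msg, "event times must lie within [0, duration]")
      }
      if (nrow(ev) && (any(ev$channel < 1L) || any(ev$channel > object@nChannels))) {
        msg <- c(msg, "channel indices must lie in 1..nChannels")
      }
    }
    if (object@duration <= 0) msg <- c(msg, "duration must be positive")
    if (object@nChannels < 1L) msg <- c(msg, "nChannels must be >= 1")
    if (length(msg)) msg else TRUE
  })

#' Construct an EventRaster
#'
#' @param time event times (s).
#' @param channel integer channel indices (1-based).
#' @param amplitude signed amplitudes (uV); NA for discrete-only rasters.
#' @param duration recording duration (s).
#' @param nChannels number of channels.
#' @return An [EventRaster-class] object (events sorted by time).
#' @export
EventRaster <- function(time, channel, amplitude = NA_real_, duration, nChannels) {
  n <- length(time)
  ev <- data.frame(time = as.numeric(time),
                   channel = as.integer(channel),
                   amplitude = rep_len(as.numeric(amplitude), n))
  ev <- ev[order(ev$time, ev$channel), , drop = FALSE]
  rownames(ev) <- NULL
  new("EventRaster", events = ev, duration = as.numeric(duration),
      nChannels = as.integer(nChannels))
}

#' Binned event raster
#'
#' Sparse channels-by-bins matrices of event counts and summed absolute
#' amplitudes, produced by [binRaster()]. Bins are half-open
#' `[k*dt, (k+1)*dt)`; an event at time t falls into bin `floor(t/dt) + 1`.
#'
#' @slot counts sparse channels x bins event counts.
#' @slot amplitudes sparse channels x bins summed |amplitude| (uV).
#' @slot binMs bin width in milliseconds.
#' @export
setClass("BinnedRaster",
  representation(counts = "Matrix", amplitudes = "Matrix", binMs = "numeric"),
  validity = function(object) {
    msg <- character(0)
    if (object@binMs <= 0) msg <- c(msg, "binMs must be positive")
    if (!identical(dim(object@counts), dim(object@amplitudes))) {
      msg <- c(msg, "counts and amplitudes must have identical dimensions")
    }
    if (length(object@counts@x) && any(object@counts@x < 0)) {
      msg <- c(msg, "counts must be non-negative")
    }
    if (length(msg)) msg else TRUE
  })

#' Empirical avalanche size distribution on finite support
#'
#' Cluster sizes together with the fitting support `[1, supportN]`, where
#' supportN is the electrode count of the array (the system-size cut-off of
#' avalanche dynamics). Sizes above supportN are retained for plotting but
#' excluded from the likelihood by the fitters.
#'
#' @slot sizes numeric vector of cluster sizes (counts for discrete mode,
#'   uV sums for continuous mode).
#' @slot supportN integer system size N (>= 2).
#' @slot mode "discrete" or "continuous".
#' @export
setClass("SizeDistribution",
  representation(sizes = "numeric", supportN = "integer", mode = "character"),
  validity = function(object) {
    msg <- character(0)
    if (object@supportN < 2L) msg <- c(msg, "supportN must be >= 2")
    if (!object@mode %in% c("discrete", "continuous")) {
      msg <- c(msg, "mode must be 'discrete' or 'continuous'")
    }
    if (!length(object@sizes)) msg <- c(msg, "at least one size required")
    if (length(object@sizes) && any(object@sizes < 1)) {
      msg <- c(msg, "sizes must be >= 1")
    }
    if (length(msg)) msg else TRUE
  })

#' Finite-support discrete power-law fit
#'
#' Result of maximising the log-likelihood of
#' `p_alpha(s) = s^alpha / sum_{x=1..N} x^alpha` over alpha.
#'
#' @slot alphaHat fitted exponent.
#' @slot supportN support size N.
#' @slot logLik maximised log-likelihood.
#' @slot nSamples number of sizes fitted.
#' @slot degenerate TRUE when the optimum pinned at a search bound.
#' @export
setClass("PowerLawFit",
  representation(alphaHat = "numeric", supportN = "integer",
                 logLik = "numeric", nSamples = "integer",
                 degenerate = "logical"))

#' Finite-support discrete exponential fit
#'
#' Maximum-likelihood fit of `p_lambda(s) = exp(-lambda*s) / sum exp(-lambda*x)`
#' on support 1..N, the null model expected for independent activity.
#'
#' @slot lambdaHat fitted rate (>= 0).
#' @slot supportN support size N.
#' @slot logLik maximised log-likelihood.
#' @slot nSamples number of sizes fitted.
#' @slot degenerate TRUE when the optimum pinned at the upper search bound.
#' @export
setClass("ExponentialFit",
  representation(lambdaHat = "numeric", supportN = "integer",
                 logLik = "numeric", nSamples = "integer",
                 degenerate = "logical"))

#' Log-likelihood-ratio model comparison
#'
#' Power law versus exponential on shared finite support, with a Vuong-type
#' normalised statistic and two-sided normal p-value.
#'
#' @slot llr log-likelihood ratio l(alphaHat) - l(lambdaHat).
#' @slot pValue two-sided p-value of the normalised statistic.
#' @slot favored "power_law", "exponential" or "undecided".
#' @slot powerLawFit the [PowerLawFit-class] component.
#' @slot exponentialFit the [ExponentialFit-class] component.
#' @export
setClass("LLRResult",
  representation(llr = "numeric", pValue = "numeric", favored = "character",
                 powerLawFit = "PowerLawFit", exponentialFit = "ExponentialFit"))

#' Kolmogorov-Smirnov distance between size distributions
#'
#' @slot dKs maximum absolute CDF difference, in [0, 1].
#' @slot reference description of the comparison distribution.
#' @export
setClass("KsDistance",
  representation(dKs = "numeric", reference = "character"),
  validity = function(object) {
    if (object@dKs < -1e-12 || object@dKs > 1 + 1e-12) "dKs must lie in [0,1]" else TRUE
  })

#' Lagged cross-correlation function
#'
#' Pearson correlation of two series as a function of time lag, optionally
#' shuffle-corrected (raw CC minus the mean CC of circularly shifted
#' surrogates).
#'
#' @slot lags lag grid in ms, symmetric about 0.
#' @slot values CC(tau) per lag.
#' @slot binMs bin width of the underlying series (ms).
#' @slot shuffleCorrected logical flag.
#' @slot pair character label of the pair.
#' @export
setClass("CcFunction",
  representation(lags = "numeric", values = "numeric", binMs = "numeric",
                 shuffleCorrected = "logical", pair = "character"),
  validity = function(object) {
    msg <- character(0)
    if (length(object@lags) != length(object@values)) {
      msg <- c(msg, "lags and values must have equal length")
    }
    if (!isTRUE(object@shuffleCorrected) &&
        any(abs(object@values) > 1 + 1e-8, na.rm = TRUE)) {
      msg <- c(msg, "raw |CC| must be <= 1")
    }
    if (length(msg)) msg else TRUE
  })

#' Zero-lag pairwise correlation matrix
#'
#' Symmetric n x n matrix of CC at tau = 0 across channels or neurons.
#' Excluded pairs (too few events or zero variance) are NA.
#'
#' @slot values symmetric numeric matrix.
#' @slot binMs bin width (ms); NA for frame-based dF/F traces.
#' @slot source one of "nlfp", "plfp", "mua", "dff".
#' @export
setClass("CcMatrix",
  representation(values = "matrix", binMs = "numeric", source = "character"),
  validity = function(object) {
    v <- object@values
    msg <- character(0)
    if (nrow(v) != ncol(v)) msg <- c(msg, "matrix must be square")
    if (nrow(v) && !isTRUE(all.equal(v, t(v), tolerance = 1e-8,
                                     check.attributes = FALSE))) {
      msg <- c(msg, "matrix must be symmetric")
    }
    if (length(msg)) msg else TRUE
  })

#' Calcium dF/F trace set
#'
#' Per-neuron fluorescence traces in percent dF/F, neurons x frames, with a
#' common frame rate. Synthetic sets carry ground truth (episode times, spike
#' counts, coupling) in `metadata`.
#'
#' @slot traces neurons x frames matrix of dF/F (%).
#' @slot frameRate frames per second.
#' @slot roiIds character ROI labels.
#' @slot metadata list of provenance/ground-truth entries.
#' @export
setClass("CalciumTraceSet",
  representation(traces = "matrix", frameRate = "numeric",
                 roiIds = "character", metadata = "list"),
  prototype(metadata = list()),
  validity = function(object) {
    msg <- character(0)
    if (length(object@frameRate) != 1L || object@frameRate <= 0) {
      msg <- c(msg, "frameRate must be a positive scalar")
    }
    if (nrow(object@traces) != length(object@roiIds)) {
      msg <- c(msg, "one roiId per trace row required")
    }
    if (length(msg)) msg else TRUE
  })

#' Construct a CalciumTraceSet
#'
#' @param traces neurons x frames matrix of dF/F (%).
#' @param frameRate frames per second (default 21.7, a typical CCD cycle).
#' @param roiIds optional ROI labels.
#' @param metadata optional list (ground truth, provenance).
#' @return A [CalciumTraceSet-class] object.
#' @export
CalciumTraceSet <- function(traces, frameRate = 21.7, roiIds = NULL,
                            metadata = list()) {
  traces <- as.matrix(traces)
  if (is.null(roiIds)) roiIds <- paste0("roi", seq_len(nrow(traces)))
  new("CalciumTraceSet", traces = traces, frameRate = frameRate,
      roiIds = as.character(roiIds), metadata = metadata)
}

#' Movement signal derived from frame-to-frame correlation
#'
#' One value per frame transition: 1 minus the Pearson correlation of
#' consecutive ROI pixel vectors (or a precomputed equivalent series).
#'
#' @slot values the movement signal, length = frames - 1 (or series length).
#' @slot fps frames per second.
#' @slot roi ROI label.
#' @export
setClass("MovementSignal",
  representation(values = "numeric", fps = "numeric", roi = "character"),
  prototype(roi = "roi"),
  validity = function(object) {
    if (length(object@fps) != 1L || object@fps <= 0) "fps must be positive" else TRUE
  })

#' Functional-connectivity stability across time segments
#'
#' Pairwise zero-lag CC vectors computed in consecutive segments and the
#' coefficient of determination (R^2) between consecutive segment pairs.
#'
#' @slot ccVectors pairs x segments matrix of CCs.
#' @slot r2 R^2 between consecutive segment pairs (length segments - 1).
#' @slot segmentLengthS segment length in seconds.
#' @export
setClass("SegmentStability",
  representation(ccVectors = "matrix", r2 = "numeric",
                 segmentLengthS = "numeric"),
  validity = function(object) {
    msg <- character(0)
    if (length(object@r2) &&
        (any(object@r2 < -1e-9, na.rm = TRUE) ||
         any(object@r2 > 1 + 1e-9, na.rm = TRUE))) {
      msg <- c(msg, "r2 values must lie in [0, 1]")
    }
    if (length(msg)) msg else TRUE
  })
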