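#' @include AllClasses.R
NULL

#' Accessors for critstate containers
#'
#' Small accessor generics over the package's S4 containers: raw samples or
#' traces, sampling/frame rates, channel/ROI labels, event tables, durations
#' and fitted parameters. Use these instead of reaching into slots.
#'
#' @param object a critstate S4 object.
#' @return The corresponding slot value (see the class documentation).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("samples", function(object) standardGeneric("samples"))
#' @rdname accessors
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setGeneric("channelIds", function(object) standardGeneric("channelIds"))
#' @rdname accessors
#' @export
setGeneric("nChannels", function(object) standardGeneric("nChannels"))
#' @rdname accessors
#' @export
setGeneric("events", function(object) standardGeneric("events"))
#' @rdname accessors
#' @export
setGeneric("duration", function(object) standardGeneric("duration"))
#' @rdname accessors
#' @export
setGeneric("binMs", function(object) standardGeneric("binMs"))
#' @rdname accessors
#' @export
setGeneric("sizes", function(object) standardGeneric("sizes"))
#' @rdname accessors
#' @export
setGeneric("supportN", function(object) standardGeneric("supportN"))
#' @rdname accessors
#' @export
setGeneric("alphaHat", function(object) standardGeneric("alphaHat"))
#' @rdname accessors
#' @export
setGeneric("lambdaHat", function(object) standardGeneric("lambdaHat"))
#' @rdname accessors
#' @export
setGeneric("fitLogLik", function(object) standardGeneric("fitLogLik"))
#' @rdname accessors
#' @export
setGeneric("traces", function(object) standardGeneric("traces"))
#' @rdname accessors
#' @export
setGeneric("frameRate", function(object) standardGeneric("frameRate"))
#' @rdname accessors
#' @export
setGeneric("roiIds", function(object) standardGeneric("roiIds"))
#' @rdname accessors
#' @export
setGeneric("metadata", function(object) standardGeneric("metadata"))
#' @rdname accessors
#' @export
setGeneric("ccValues", function(object) standardGeneric("ccValues"))
#' @rdname accessors
#' @export
setGeneric("ccLags", function(object) standardGeneric("ccLags"))

#' @rdname accessors
setMethod("samples", "TimeSeriesRecording", function(object) object@samples)
#' @rdname accessors
setMethod("samplingRate", "TimeSeriesRecording", function(object) object@samplingRate)
#' @rdname accessors
setMethod("channelIds", "TimeSeriesRecording", function(object) object@channelIds)
#' @rdname accessors
setMethod("nChannels", "TimeSeriesRecording", function(object) nrow(object@samples))
#' @rdname accessors
setMethod("duration", "TimeSeriesRecording",
          function(object) ncol(object@samples) / object@samplingRate)

#' @rdname accessors
setMethod("events", "EventRaster", function(object) object@events)
#' @rdname accessors
setMethod("duration", "EventRaster", function(object) object@duration)
#' @rdname accessors
setMethod("nChannels", "EventRaster", function(object) object@nChannels)

#' @rdname accessors
setMethod("binMs", "BinnedRaster", function(object) object@binMs)
#' @rdname accessors
setMethod("nChannels", "BinnedRaster", function(object) nrow(object@counts))

#' @rdname accessors
setMethod("sizes", "SizeDistribution", function(object) object@sizes)
#' @rdname accessors
setMethod("supportN", "SizeDistribution", function(object) object@supportN)

#' @rdname accessors
setMethod("alphaHat", "PowerLawFit", function(object) object@alphaHat)
#' @rdname accessors
setMethod("supportN", "PowerLawFit", function(object) object@supportN)
#' @rdname accessors
setMethod("fitLogLik", "PowerLawFit", function(object) object@logLik)
#' @rdname accessors
setMethod("lambdaHat", "ExponentialFit", function(object) object@lambdaHat)
#' @rdname accessors
setMethod("supportN", "ExponentialFit", function(object) object@supportN)
#' @rdname accessors
setMethod("fitLogLik", "ExponentialFit", function(object) object@logLik)

#' @rdname accessors
setMethod("traces", "CalciumTraceSet", function(object) object@traces)
#' @rdname accessors
setMethod("frameRate", "CalciumTraceSet", function(object) object@frameRate)
#' @rdname accessors
setMethod("roiIds", "CalciumTraceSet", function(object) object@roiIds)
#' @rdname accessors
setMethod("metadata", "CalciumTraceSet", function(object) object@metadata)
#' @rdname accessors
setMethod("duration", "CalciumTraceSet",
          function(object) ncol(object@traces) / object@frameRate)

#' @rdname accessors
setMethod("ccValues", "CcFunction", function(object) object@values)
#' @rdname accessors
setMethod("ccLags", "CcFunction", function(object) object@lags)
#' @rdname accessors
setMethod("ccValues", "CcMatrix", function(object) object@values)

#' @rdname accessors
setMethod("samples", "MovementSignal", function(object) object@values)
#' @rdname accessors
setMethod("duration", "MovementSignal",
          function(object) length(object@values) / object@fps)

setMethod("show", "TimeSeriesRecording", function(object) {
  cat(sprintf("TimeSeriesRecording: %d channel(s) x %d samples @ %g Hz (%.2f s)\n",
              nrow(object@samples), ncol(object@samples), object@samplingRate,
              ncol(object@samples) / object@samplingRate))
})

setMethod("show", "EventRaster", function(object) {
  cat(sprintf("EventRaster: %d event(s) on %d channel(s) over %.2f s\n",
              nrow(object@events), object@nChannels, object@duration))
})

setMethod("show", "BinnedRaster", function(object) {
  cat(sprintf("BinnedRaster: %d channel(s) x %d bins @ %g ms (%d events)\n",
              nrow(object@counts), ncol(object@counts), object@binMs,
              as.integer(sum(object@counts))))
})

setMethod("show", "SizeDistribution", function(object) {
  cat(sprintf("SizeDistribution (%s): %d cluster(s), support N = %d, %d above cut-off\n",
              object@mode, length(object@sizes), object@supportN,
              sum(object@sizes > object@supportN)))
})

setMethod("show", "PowerLawFit", function(object) {
  cat(sprintf("PowerLawFit: alpha = %.4f (N = %d, n = %d, logLik = %.2f)%s\n",
              object@alphaHat, object@supportN, object@nSamples, object@logLik,
              if (object@degenerate) " [degenerate: at search bound]" else ""))
})

setMethod("show", "ExponentialFit", function(object) {
  cat(sprintf("ExponentialFit: lambda = %.4f (N = %d, n = %d, logLik = %.2f)%s\n",
              object@lambdaHat, object@supportN, object@nSamples, object@logLik,
              if (object@degenerate) " [degenerate: at search bound]" else ""))
})

setMethod("show", "LLRResult", function(object) {
  cat(sprintf("LLR = %.2f, p = %.3g, favored: %s\n",
              object@llr, object@pValue, object@favored))
})

setMethod("show", "KsDistance", function(object) {
  cat(sprintf("D_KS = %.4f (vs %s)\n", object@dKs, object@reference))
})

setMethod("show", "CcFunction", function(object) {
  cat(sprintf("CcFunction%s: %d lag(s) in [%g, %g] ms, CC(0) = %.3f\n",
              if (object@shuffleCorrected) " (shuffle-corrected)" else "",
              length(object@lags), min(object@lags), max(object@lags),
              object@values[which.min(abs(object@lags))]))
})

setMethod("show", "CcMatrix", function(object) {
  v <- object@values
  off <- v[upper.tri(v)]
  cat(sprintf("CcMatrix (%s): %d x %d, mean pairwise CC = %.4f (%d excluded pair(s))\n",
              object@source, nrow(v), ncol(v), mean(off, na.rm = TRUE),
              sum(is.na(off))))
})

setMethod("show", "CalciumTraceSet", function(object) {
  cat(sprintf("CalciumTraceSet: %d neuron(s) x %d frames @ %g fps (%.1f s)\n",
              nrow(object@traces), ncol(object@traces), object@frameRate,
              ncol(object@traces) / object@frameRate))
})

setMethod("show", "MovementSignal", function(object) {
  cat(sprintf("MovementSignal: %d frame(s) @ %g fps (roi '%s')\n",
              length(object@values), object@fps, object@roi))
})

setMethod("show", "SegmentStability", function(object) {
  cat(sprintf("SegmentStability: %d pair(s) x %d segment(s) of %g s; R2 = %s\n",
              nrow(object@ccVectors), ncol(object@ccVectors),
              object@segmentLengthS,
              paste(sprintf("%.3f", object@r2), collapse = ", ")))
})
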