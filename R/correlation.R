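#' @include AllClasses.R utils.R
NULL

# Pearson correlation of x_t with y_{t+tau} over the overlapping range;
# lagBins >= 0 shifts y forward.
lagCor <- function(x, y, lagBins) {
  n <- length(x)
  if (lagBins >= 0) {
    ix <- seq_len(n - lagBins)
    cor(x[ix], y[ix + lagBins])
  } else {
    ix <- seq_len(n + lagBins)
    cor(x[ix - lagBins], y[ix])
  }
}

#' Lagged cross-correlation function
#'
#' `CC(tau) = E[(x_t - mu_x)(y_{t+tau} - mu_y)] / (sigma_x sigma_y)`,
#' computed as the Pearson correlation over the overlapping range at each
#' lag. Series are binned count rasters or continuous dF/F traces sampled at
#' `binMs` resolution.
#'
#' @param x,y numeric series of equal length (counts per bin or samples).
#' @param binMs bin/sample width (ms).
#' @param maxLagMs maximum |lag| (ms).
#' @param pair optional pair label.
#' @return A [CcFunction-class]. Zero-variance input is an error (exclude
#'   such pairs upstream).
#' @examples
#' ccFunction(c(0, 1, 0, 1), c(1, 0, 1, 0), binMs = 1, maxLagMs = 1)
#' @export
ccFunction <- function(x, y, binMs, maxLagMs = 0, pair = "x:y") {
  if (length(x) != length(y)) stop("series lengths differ", call. = FALSE)
  if (sd(x) < 1e-14 || sd(y) < 1e-14) {
    stop("zero-variance series: pair must be excluded", call. = FALSE)
  }
  maxLagBins <- floor(maxLagMs / binMs)
  lagBins <- seq(-maxLagBins, maxLagBins)
  vals <- vapply(lagBins, function(l) lagCor(x, y, l), numeric(1))
  new("CcFunction", lags = lagBins * binMs, values = vals, binMs = binMs,
      shuffleCorrected = FALSE, pair = pair)
}

#' Shuffle-corrected cross-correlation
#'
#' Raw CC minus the mean CC of surrogate pairs, averaged over `nShuffles`
#' repetitions (default 10). Each surrogate circularly shifts the two series
#' by independent uniform offsets, preserving rate and autostructure while
#' destroying their temporal relation, so chance correlation induced by
#' rates alone is removed.
#'
#' @inheritParams ccFunction
#' @param nShuffles surrogate repetitions (default 10).
#' @param seed RNG seed for the shifts.
#' @return A [CcFunction-class] with `shuffleCorrected = TRUE` (values may
#'   leave [-1, 1] slightly by construction).
#' @export
shuffleCorrectedCC <- function(x, y, binMs, maxLagMs = 0, nShuffles = 10,
                               seed = 1, pair = "x:y") {
  raw <- ccFunction(x, y, binMs, maxLagMs, pair = pair)
  n <- length(x)
  maxLagBins <- floor(maxLagMs / binMs)
  lagBins <- seq(-maxLagBins, maxLagBins)
  shufMean <- withSeed(seed, {
    acc <- numeric(length(lagBins))
    for (r in seq_len(nShuffles)) {
      sx <- circShift(x, sample.int(n, 1L))
      sy <- circShift(y, sample.int(n, 1L))
      acc <- acc + vapply(lagBins, function(l) lagCor(sx, sy, l), numeric(1))
    }
    acc / nShuffles
  })
  new("CcFunction", lags = raw@lags, values = raw@values - shufMean,
      binMs = binMs, shuffleCorrected = TRUE, pair = pair)
}

circShift <- function(v, k) {
  n <- length(v)
  k <- k %% n
  if (k == 0) v else c(v[(n - k + 1L):n], v[seq_len(n - k)])
}

#' Zero-lag pairwise correlation matrix
#'
#' Computes CC at tau = 0 for every channel/neuron pair of a binned raster
#' or a dF/F trace set. Count-raster pairs can be shuffle-corrected; dF/F
#' trace correlations are computed raw. Series with fewer than `minEvents`
#' events (count rasters) or zero variance are excluded (NA row/column
#' entries).
#'
#' @param object a [BinnedRaster-class] or [CalciumTraceSet-class].
#' @param source label: "nlfp", "plfp", "mua" or "dff" (defaults by class).
#' @param corrected apply shuffle correction per pair (count rasters only).
#' @param nShuffles,seed shuffle parameters when `corrected`.
#' @param minEvents minimum event count per series for count rasters
#'   (default 10).
#' @return A [CcMatrix-class].
#' @export
ccMatrix <- function(object, source = NULL, corrected = FALSE, nShuffles = 10,
                     seed = 1, minEvents = 10) {
  if (is(object, "BinnedRaster")) {
    mat <- as.matrix(object@counts)
    if (is.null(source)) source <- "nlfp"
    valid <- Matrix::rowSums(object@counts) >= minEvents &
      apply(mat, 1L, sd) > 1e-14
    bm <- object@binMs
  } else if (is(object, "CalciumTraceSet")) {
    mat <- traces(object)
    if (is.null(source)) source <- "dff"
    corrected <- FALSE   # dF/F correlations are raw by convention
    valid <- apply(mat, 1L, sd) > 1e-14
    bm <- 1000 / frameRate(object)
  } else {
    stop("unsupported input class", call. = FALSE)
  }
  k <- nrow(mat)
  vals <- matrix(NA_real_, k, k)
  diag(vals) <- 1
  vIdx <- which(valid)
  if (length(vIdx) >= 2) {
    sub <- cor(t(mat[vIdx, , drop = FALSE]))
    vals[vIdx, vIdx] <- sub
    if (corrected) {
      for (a in seq_along(vIdx)[-length(vIdx)]) {
        for (b in (a + 1L):length(vIdx)) {
          cc <- shuffleCorrectedCC(mat[vIdx[a], ], mat[vIdx[b], ], binMs = bm,
                                   maxLagMs = 0, nShuffles = nShuffles,
                                   seed = subSeed(seed, paste0(a, "_", b)))
          vals[vIdx[a], vIdx[b]] <- vals[vIdx[b], vIdx[a]] <- ccValues(cc)
        }
      }
    }
  }
  new("CcMatrix", values = vals, binMs = bm, source = source)
}

#' Mean pairwise correlation
#'
#' Average CC over all valid (non-NA) off-diagonal pairs at tau = 0 - the
#' summary statistic reported per condition.
#'
#' @param m a [CcMatrix-class] (or plain symmetric matrix).
#' @return Scalar mean; error if no valid pair exists.
#' @export
meanPairwiseCC <- function(m) {
  v <- if (is(m, "CcMatrix")) ccValues(m) else m
  off <- v[upper.tri(v)]
  off <- off[!is.na(off)]
  if (!length(off)) stop("no valid pair", call. = FALSE)
  mean(off)
}

#' Half-width of a cross-correlation peak
#'
#' Full width at half of the zero-lag peak above baseline, divided by two.
#' Baseline is the mean CC at |tau| >= 0.8 * max lag; crossings of the
#' half level are linearly interpolated between lag samples. Undefined
#' (NA, with `attr(, "flag")`) when the peak is not at zero lag or does not
#' exceed the baseline.
#'
#' @param cc a [CcFunction-class] with symmetric lags.
#' @return Half-width in ms, or NA with a flag attribute.
#' @export
ccHalfWidth <- function(cc) {
  stopifnot(is(cc, "CcFunction"))
  lags <- ccLags(cc); vals <- ccValues(cc)
  maxLag <- max(abs(lags))
  if (maxLag == 0) stop("need lags beyond 0 to measure a width", call. = FALSE)
  i0 <- which.min(abs(lags))
  if (which.max(vals) != i0) {
    out <- NA_real_; attr(out, "flag") <- "peak_not_at_zero"; return(out)
  }
  base <- mean(vals[abs(lags) >= 0.8 * maxLag])
  peak <- vals[i0]
  if (!(peak > base)) {
    out <- NA_real_; attr(out, "flag") <- "peak_below_baseline"; return(out)
  }
  half <- base + (peak - base) / 2
  crossAt <- function(idx) {   # idx runs from the peak outwards
    for (j in seq_along(idx)[-1L]) {
      a <- idx[j - 1L]; b <- idx[j]
      if (vals[b] <= half) {
        frac <- (vals[a] - half) / (vals[a] - vals[b])
        return(abs(lags[a] + frac * (lags[b] - lags[a])))
      }
    }
    maxLag
  }
  right <- crossAt(i0:length(lags))
  left <- crossAt(i0:1)
  (right + left) / 2   # FWHM / 2
}

#' Relative synchrony
#'
#' Ratio of striatal mean pairwise CC to cortical mean pairwise CC; the sign
#' is preserved. Errors when the denominator is numerically zero.
#'
#' @param striatalMeanCc,corticalMeanCc scalar mean CCs.
#' @return Scalar ratio.
#' @export
relativeSynchrony <- function(striatalMeanCc, corticalMeanCc) {
  assertScalar(striatalMeanCc, "striatalMeanCc")
  if (!is.numeric(corticalMeanCc) || abs(corticalMeanCc) < 1e-6) {
    stop("cortical mean CC is (numerically) zero", call. = FALSE)
  }
  striatalMeanCc / corticalMeanCc
}
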