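#' @include AllClasses.R
NULL

#' Bin an event raster
#'
#' Assigns each event to a half-open time bin `[k*dt, (k+1)*dt)` (an event at
#' time t goes to bin `floor(t/dt) + 1`; events exactly at the recording end
#' are clamped into the last bin). Multiple events per channel-bin are kept
#' as counts; absolute amplitudes are summed per channel-bin for continuous
#' (uV) cluster sizes.
#'
#' @param raster an [EventRaster-class].
#' @param binMs bin width dt in milliseconds (2-4 ms is typical for nLFP
#'   rasters).
#' @return A [BinnedRaster-class].
#' @export
binRaster <- function(raster, binMs) {
  stopifnot(is(raster, "EventRaster"))
  assertScalar(binMs, "binMs", lower = 0, strictLower = TRUE)
  nBins <- max(1L, as.integer(ceiling(duration(raster) * 1000 / binMs)))
  nCh <- nChannels(raster)
  ev <- events(raster)
  if (!nrow(ev)) {
    z <- sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                      dims = c(nCh, nBins))
    return(new("BinnedRaster", counts = z, amplitudes = z, binMs = binMs))
  }
  bin <- pmin(as.integer(floor(ev$time * 1000 / binMs)) + 1L, nBins)
  counts <- sparseMatrix(i = ev$channel, j = bin, x = rep(1, nrow(ev)),
                         dims = c(nCh, nBins))
  absAmp <- abs(ev$amplitude)
  absAmp[is.na(absAmp)] <- 0
  amps <- sparseMatrix(i = ev$channel, j = bin, x = absAmp,
                       dims = c(nCh, nBins))
  new("BinnedRaster", counts = counts, amplitudes = amps, binMs = binMs)
}

#' Extract spatiotemporal clusters (avalanches)
#'
#' A cluster is a maximal run of consecutive non-empty bins (non-empty =
#' at least one event on any channel), terminated by at least one fully
#' empty bin on each side (or the raster boundary). The discrete size is the
#' event count in the cluster; the continuous size is the summed absolute
#' amplitude in uV.
#'
#' @param binned a [BinnedRaster-class].
#' @return data.frame with columns `startBin`, `nBins`, `sizeDiscrete`,
#'   `sizeContinuous`; zero rows when the raster is empty.
#' @export
extractClusters <- function(binned) {
  stopifnot(is(binned, "BinnedRaster"))
  perBin <- Matrix::colSums(binned@counts)
  occ <- perBin > 0
  if (!any(occ)) {
    return(data.frame(startBin = integer(0), nBins = integer(0),
                      sizeDiscrete = numeric(0), sizeContinuous = numeric(0)))
  }
  r <- rle(occ)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  starts <- starts[keep]; ends <- ends[keep]
  csCounts <- c(0, cumsum(perBin))
  csAmps <- c(0, cumsum(Matrix::colSums(binned@amplitudes)))
  data.frame(
    startBin = as.integer(starts),
    nBins = as.integer(ends - starts + 1L),
    sizeDiscrete = csCounts[ends + 1L] - csCounts[starts],
    sizeContinuous = csAmps[ends + 1L] - csAmps[starts]
  )
}

#' Cluster rate and mean duration
#'
#' @param clusters cluster table from [extractClusters()].
#' @param durationS recording duration (s).
#' @param binMs bin width (ms) used for clustering.
#' @return list with `rate` (clusters/s), `meanDurationMs`, and `n`.
#' @export
clusterStatistics <- function(clusters, durationS, binMs) {
  assertScalar(durationS, "durationS", lower = 0, strictLower = TRUE)
  list(rate = nrow(clusters) / durationS,
       meanDurationMs = if (nrow(clusters)) mean(clusters$nBins) * binMs else NA_real_,
       n = nrow(clusters))
}

#' Build a size distribution from clusters
#'
#' Collects discrete (event-count) or continuous (uV) cluster sizes together
#' with the fitting support `[1, supportN]`. Sizes above the cut-off remain
#' in the object (for plotting and KS comparisons across conditions) but are
#' excluded from the likelihood by the MLE fitters; use [supportSizes()] to
#' obtain the truncated vector.
#'
#' @param clusters cluster table from [extractClusters()] or a numeric vector
#'   of sizes.
#' @param supportN system size N (electrode count, >= 2).
#' @param mode "discrete" or "continuous".
#' @return A [SizeDistribution-class].
#' @export
sizeDistribution <- function(clusters, supportN, mode = c("discrete", "continuous")) {
  mode <- match.arg(mode)
  s <- if (is.data.frame(clusters)) {
    if (mode == "discrete") clusters$sizeDiscrete else clusters$sizeContinuous
  } else {
    as.numeric(clusters)
  }
  if (!length(s)) stop("no clusters: cannot build a size distribution", call. = FALSE)
  new("SizeDistribution", sizes = as.numeric(s), supportN = as.integer(supportN),
      mode = mode)
}

#' Sizes within the fitting support
#'
#' @param dist a [SizeDistribution-class].
#' @return Numeric vector of the sizes within `[1, supportN]` (the fitting
#'   range); the count of excluded above-cut-off sizes is in
#'   `attr(, "nAboveCutoff")`.
#' @export
supportSizes <- function(dist) {
  stopifnot(is(dist, "SizeDistribution"))
  s <- sizes(dist)
  out <- s[s <= supportN(dist)]
  attr(out, "nAboveCutoff") <- sum(s > supportN(dist))
  out
}

#' Empirical PMF of a discrete size distribution
#'
#' @param dist a [SizeDistribution-class] in discrete mode.
#' @return data.frame with `size` (1..max observed) and `prob` (sums to 1).
#' @export
sizePmf <- function(dist) {
  stopifnot(is(dist, "SizeDistribution"), dist@mode == "discrete")
  s <- as.integer(round(sizes(dist)))
  tab <- tabulate(s, nbins = max(s))
  data.frame(size = seq_along(tab), prob = tab / sum(tab))
}
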