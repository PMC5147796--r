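#' @include AllClasses.R
NULL

# Columnar text interchange: '#'-prefixed key: value header lines followed by
# a TSV body. Headers must declare the metadata needed to reconstruct the
# object losslessly.

readHeader <- function(path) {
  lines <- readLines(path, n = 50L)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("^#\\s*([A-Za-z0-9_]+)\\s*:\\s*(.*)$", h))[[1]]
    if (length(m) == 3L) kv[[m[2]]] <- trimws(m[3])
  }
  kv
}

#' Read / write multichannel time series
#'
#' Text format: header lines `# sampling_rate_hz:`, `# units:`, `# t0_s:`,
#' `# channels:` (comma-separated labels), then one TSV column per channel.
#' The round-trip is lossless to the printed precision; missing rate or
#' units on read is an error.
#'
#' @param ts a [TimeSeriesRecording-class] (write).
#' @param path file path.
#' @param units unit label written to the header (default "uV").
#' @return `readTimeSeries` returns a [TimeSeriesRecording-class];
#'   `writeTimeSeries` returns `path` invisibly.
#' @export
writeTimeSeries <- function(ts, path, units = "uV") {
  stopifnot(is(ts, "TimeSeriesRecording"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# sampling_rate_hz: %.10g", samplingRate(ts)),
    sprintf("# units: %s", units),
    sprintf("# t0_s: %.10g", ts@t0),
    sprintf("# channels: %s", paste(channelIds(ts), collapse = ","))
  ), con)
  write.table(t(samples(ts)), con, sep = "\t", row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname writeTimeSeries
#' @export
readTimeSeries <- function(path) {
  kv <- readHeader(path)
  if (is.null(kv$sampling_rate_hz) || is.null(kv$units)) {
    stop("header must declare sampling_rate_hz and units", call. = FALSE)
  }
  body <- read.table(path, sep = "\t", comment.char = "#")
  chans <- strsplit(kv$channels, ",")[[1]]
  mat <- t(as.matrix(body))
  if (length(chans) != nrow(mat)) {
    stop("channel count mismatch between header and body", call. = FALSE)
  }
  TimeSeriesRecording(mat, samplingRate = as.numeric(kv$sampling_rate_hz),
                      channelIds = chans,
                      t0 = if (is.null(kv$t0_s)) 0 else as.numeric(kv$t0_s))
}

#' Read / write event rasters
#'
#' Text format: header lines `# duration_s:` and `# n_channels:`, then TSV
#' columns `time_s`, `channel`, and optionally `amplitude_uv` (omitted for
#' discrete-only MUA rasters). Events are sorted by time on read, with a
#' warning when the input was unsorted.
#'
#' @param raster an [EventRaster-class] (write).
#' @param path file path.
#' @return `readRaster` returns an [EventRaster-class]; `writeRaster`
#'   returns `path` invisibly.
#' @export
writeRaster <- function(raster, path) {
  stopifnot(is(raster, "EventRaster"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# duration_s: %.10g", duration(raster)),
    sprintf("# n_channels: %d", nChannels(raster))
  ), con)
  ev <- events(raster)
  hasAmp <- !all(is.na(ev$amplitude))
  cols <- if (hasAmp) ev else ev[, c("time", "channel")]
  names(cols) <- if (hasAmp) c("time_s", "channel", "amplitude_uv")
                 else c("time_s", "channel")
  write.table(cols, con, sep = "\t", row.names = FALSE, col.names = TRUE,
              quote = FALSE)
  invisible(path)
}

#' @rdname writeRaster
#' @export
readRaster <- function(path) {
  kv <- readHeader(path)
  if (is.null(kv$duration_s) || is.null(kv$n_channels)) {
    stop("header must declare duration_s and n_channels", call. = FALSE)
  }
  body <- read.table(path, sep = "\t", comment.char = "#", header = TRUE)
  if (!all(c("time_s", "channel") %in% names(body))) {
    stop("body must have time_s and channel columns", call. = FALSE)
  }
  if (is.unsorted(body$time_s)) {
    warning("events were not sorted by time; sorting on read")
  }
  amp <- if ("amplitude_uv" %in% names(body)) body$amplitude_uv else NA_real_
  EventRaster(body$time_s, body$channel, amp,
              duration = as.numeric(kv$duration_s),
              nChannels = as.integer(kv$n_channels))
}

#' Read / write calcium trace sets
#'
#' CSV with a `# frame_rate_hz:` header line and one column per ROI
#' (header row of ROI ids), frames as rows.
#'
#' @param cts a [CalciumTraceSet-class] (write).
#' @param path file path.
#' @return `readTraces` returns a [CalciumTraceSet-class]; `writeTraces`
#'   returns `path` invisibly.
#' @export
writeTraces <- function(cts, path) {
  stopifnot(is(cts, "CalciumTraceSet"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# frame_rate_hz: %.10g", frameRate(cts)), con)
  body <- as.data.frame(t(traces(cts)))
  names(body) <- roiIds(cts)
  write.table(body, con, sep = ",", row.names = FALSE, col.names = TRUE,
              quote = FALSE)
  invisible(path)
}

#' @rdname writeTraces
#' @export
readTraces <- function(path) {
  kv <- readHeader(path)
  if (is.null(kv$frame_rate_hz)) {
    stop("header must declare frame_rate_hz", call. = FALSE)
  }
  body <- read.table(path, sep = ",", comment.char = "#", header = TRUE,
                     check.names = FALSE)
  CalciumTraceSet(t(as.matrix(body)), frameRate = as.numeric(kv$frame_rate_hz),
                  roiIds = names(body))
}
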