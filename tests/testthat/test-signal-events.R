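# Filtering and event extraction from continuous signals.

makeTone <- function(freq, fs = 1000, dur = 5) {
  t <- seq(1 / fs, dur, by = 1 / fs)
  sin(2 * pi * freq * t)
}

test_that("band-pass keeps in-band tones and attenuates out-of-band tones", {
  ts <- TimeSeriesRecording(rbind(makeTone(25), makeTone(200)), 1000)
  f <- bandpassFilter(ts, 1, 50)
  mid <- 1000:4000  # avoid filter edge transients
  expect_equal(max(abs(samples(f)[1, mid])), 1, tolerance = 0.05)
  att <- 20 * log10(max(abs(samples(f)[2, mid])))
  expect_lt(att, -20)
})

test_that("filtering is zero-phase: a symmetric pulse keeps its peak sample", {
  n <- 5000
  p <- exp(-((seq_len(n) - 2500) / 30)^2)
  f <- bandpassFilter(TimeSeriesRecording(matrix(p, 1), 1000), 1, 100)
  expect_lte(abs(which.max(samples(f)[1, ]) - 2500), 1)
})

test_that("invalid bands are rejected", {
  ts <- TimeSeriesRecording(matrix(rnorm(1000), 1), 1000)
  expect_error(bandpassFilter(ts, 50, 10), "invalid band")
  expect_error(bandpassFilter(ts, 1, 600), "invalid band")
})

test_that("channel SD estimation: modes differ on bursty signals, constants flagged", {
  set.seed(2)
  quiet <- rnorm(2000)
  bursty <- c(quiet, rnorm(2000, sd = 8))
  ts <- TimeSeriesRecording(rbind(bursty, rep(1, 4000)), 1000)
  full <- estimateChannelSD(ts, "full_signal")
  basew <- estimateChannelSD(ts, "baseline_window", windowS = 2, windowStartS = 0)
  expect_equal(unname(basew[1]), 1, tolerance = 0.1)
  expect_gt(full[1], basew[1])
  expect_true(is.na(full[2]))
  expect_identical(attr(full, "excluded"), 2L)
})

test_that("one event per excursion, at the signed extremum", {
  # single clean deflection
  x <- rep(0, 1000); x[500:520] <- -5 * sin(seq(0, pi, length.out = 21))
  ts <- TimeSeriesRecording(matrix(x, 1), 1000)
  ev <- events(detectLfpEvents(ts, z = -4.5, sds = 1))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$time, (500 + 9) / 1000, tolerance = 2e-3)
  expect_lt(ev$amplitude, -4.9)

  # two sub-threshold-separated minima in one excursion: one event at the deeper
  y <- rep(0, 200)
  y[50:70] <- -6; y[71:75] <- -5; y[76:90] <- -8
  ts2 <- TimeSeriesRecording(matrix(y, 1), 1000)
  ev2 <- events(detectLfpEvents(ts2, z = -4.5, sds = 1))
  expect_equal(nrow(ev2), 1)
  expect_equal(ev2$amplitude, -8)

  # positive polarity mirrors the rule
  ev3 <- events(detectLfpEvents(TimeSeriesRecording(matrix(-y, 1), 1000),
                                z = 2.5, polarity = "positive", sds = 1))
  expect_equal(nrow(ev3), 1)
  expect_equal(ev3$amplitude, 8)
})

test_that("detection is sign-symmetric and monotone in |z|", {
  set.seed(14)
  r <- EventRaster(seq(0.5, 19.5, 0.5), sample(1:3, 39, TRUE),
                   -rlnorm(39, log(30), 0.5), duration = 20, nChannels = 3)
  lfp <- synthLfpFromRaster(r, noiseSd = 3, seed = 15)
  neg <- events(detectLfpEvents(lfp, z = -4.5, sds = rep(3, 3)))
  flipped <- TimeSeriesRecording(-samples(lfp), samplingRate(lfp))
  pos <- events(detectLfpEvents(flipped, z = 4.5, polarity = "positive",
                                sds = rep(3, 3)))
  expect_equal(neg$time, pos$time)
  expect_equal(neg$amplitude, -pos$amplitude)

  counts <- vapply(c(2, 3, 4.5, 6), function(z) {
    nrow(events(detectLfpEvents(lfp, z = -z, sds = rep(3, 3))))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("MUA thresholding applies the dead-time merge and rms ~ sd on zero-mean noise", {
  # two crossings 0.4 ms apart at 10 kHz merge under a 1 ms dead time
  set.seed(3)
  x <- rnorm(1000, sd = 0.1)
  x[100:101] <- x[100:101] - 10; x[104:105] <- x[104:105] - 9
  ts <- TimeSeriesRecording(matrix(x, 1), 10000)
  ev <- events(detectMuaEvents(ts, rule = "sd", k = -5, deadTimeMs = 1))
  expect_equal(nrow(ev), 1)

  set.seed(4)
  z <- rnorm(5000)
  sdThr <- sd(z); rmsThr <- sqrt(mean(z^2))
  expect_equal(sdThr, rmsThr, tolerance = 0.02)
})

test_that("spike-train template is fully recovered at -5 SD", {
  set.seed(6)
  fs <- 10000
  x <- rnorm(fs, sd = 1)
  at <- seq(500, 9500, by = 500)
  for (a in at) x[a:(a + 4)] <- x[a:(a + 4)] - 8 * c(0.4, 1, 0.7, 0.3, 0.1)
  ts <- TimeSeriesRecording(matrix(x, 1), fs)
  ev <- events(detectMuaEvents(ts, k = -5))
  expect_equal(nrow(ev), length(at))
})

test_that("triggered average recovers embedded deflections and stays in the band for random triggers", {
  set.seed(21)
  r <- EventRaster(seq(1, 29, 1), rep(1, 29), rep(-50, 29),
                   duration = 30, nChannels = 1)
  lfp <- synthLfpFromRaster(r, noiseSd = 2, seed = 22)
  ta <- triggeredAverage(lfp, events(r)$time, windowS = 0.05, nShuffles = 50,
                         seed = 23)
  mid <- which.min(abs(ta$lagS))
  expect_lt(ta$average[mid], -40)           # deflection recovered
  expect_lt(ta$average[mid], ta$bandLo[mid])  # far outside the shuffle band

  # random triggers on pure noise stay inside the band
  noise <- TimeSeriesRecording(matrix(rnorm(30000, sd = 2), 1), 1000)
  tt <- runif(20, 1, 29)
  ta0 <- triggeredAverage(noise, tt, windowS = 0.05, nShuffles = 100, seed = 24)
  inBand <- mean(ta0$average > ta0$bandLo & ta0$average < ta0$bandHi)
  expect_gt(inBand, 0.95)

  # single trigger equals the windowed snippet
  ta1 <- triggeredAverage(noise, 5, windowS = 0.02, nShuffles = 5, seed = 25)
  snip <- samples(noise)[1, (5001 - 20):(5001 + 20)]
  expect_equal(ta1$average, snip)

  expect_error(triggeredAverage(noise, 0.001, windowS = 0.05), "window")
})

test_that("event-locked PSD is unit-area and concentrates power at the tone frequency", {
  ts <- TimeSeriesRecording(matrix(makeTone(10), 1), 1000)
  ps <- normalizedPsd(ts, eventTimes = c(1, 2, 3), windowS = 0.5)
  df <- diff(ps$freqHz[1:2])
  expect_equal(sum(ps$density) * df, 1, tolerance = 1e-9)
  expect_equal(ps$freqHz[which.max(ps$density)], 10)

  # white noise: roughly flat density away from DC
  set.seed(9)
  wn <- TimeSeriesRecording(matrix(rnorm(20000), 1), 1000)
  pw <- normalizedPsd(wn, eventTimes = seq(1, 19, 1), windowS = 0.5)
  body <- pw$density[pw$freqHz > 5 & pw$freqHz < 495]
  expect_lt(sd(body) / mean(body), 1)  # no dominant peak
  expect_error(normalizedPsd(wn, eventTimes = numeric(0)), "window")
})
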