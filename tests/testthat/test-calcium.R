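# dF/F pipeline: baseline, transient detection, regression, stability.

test_that("dF/F follows subtract-then-normalize in percent units", {
  expect_equal(computeDFF(110, 100), 10)
  expect_equal(computeDFF(100, 100), 0)
  expect_equal(computeDFF(130, 100, fBackground = 20), 10)
  bad <- computeDFF(c(110, 110), c(100, -5))
  expect_true(is.na(bad[2]))
  expect_equal(attr(bad, "invalidFrames"), 2L)
})

test_that("rolling baseline is the lower-half mean and tracks the noise floor", {
  # a window holding values 1..10 averages its 5 smallest to 3
  bl <- rollingBaseline(1:10, frameRate = 1, windowS = 10)
  expect_equal(bl[5], 3)

  expect_equal(rollingBaseline(rep(4.2, 100), 10, windowS = 5), rep(4.2, 100))

  # sparse positive transients barely move the baseline
  set.seed(8)
  noise <- rnorm(2000, sd = 1)
  spiky <- noise
  at <- seq(100, 1900, by = 200)
  for (a in at) spiky[a:(a + 10)] <- spiky[a:(a + 10)] + 20
  bl2 <- rollingBaseline(spiky, frameRate = 21.7, windowS = 30)
  expect_lt(max(abs(bl2 - mean(noise))), 1)  # stays within one noise SD
})

test_that("summated-increment detector finds one peak per rising epoch at the epoch maximum", {
  # monotone rise of 5 frames x 2%/frame, threshold 6% -> one peak of 10%
  dff <- c(0, 2, 4, 6, 8, 10, 9, 5, 2, 0)
  pk <- detectCaPeaks(dff, threshold = 6)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$amplitude, 10)
  expect_equal(pk$frame, 6)

  expect_equal(nrow(detectCaPeaks(rep(3, 50), threshold = 1)), 0)
})

test_that("peak count is monotone non-increasing in the threshold", {
  set.seed(9)
  dff <- rnorm(5000)
  counts <- vapply(c(1, 2, 4, 6, 8), function(th) {
    nrow(detectCaPeaks(dff, threshold = th))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("baseline removal plus dF/F recovers known amplitudes on noiseless traces", {
  fr <- 21.7
  n <- 3000
  f0 <- 100
  raw <- rep(f0, n)
  at <- seq(300, 2700, by = 300)
  kern <- 15 * exp(-(0:40) / (0.5 * fr))
  for (a in at) raw[a:(a + 40)] <- raw[a:(a + 40)] + kern
  bl <- rollingBaseline(raw, fr, windowS = 30)
  dff <- computeDFF(raw, bl)
  pk <- detectCaPeaks(dff, threshold = 5)
  expect_equal(nrow(pk), length(at))
  expect_equal(pk$amplitude, rep(15, length(at)), tolerance = 0.15)
})

test_that("spike-amplitude regression is exact on linear data and anchored at 2 spikes", {
  counts <- rep(1:4, each = 6)
  neurons <- rep(rep(c("a", "b", "c"), 2), 4)
  amps <- ifelse(neurons == "a", 4, ifelse(neurons == "b", 6, 8)) * counts
  fit <- spikeDffRegression(counts, amps, neurons)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  expect_equal(fit$slope, 0.5, tolerance = 1e-12)  # normalized: 2 spikes = 1
  twoSpike <- fit$table[fit$table$k == 2, "norm"]
  expect_true(all(abs(twoSpike - 1) < 1e-12))

  # a neuron without 2-spike events is excluded and flagged
  keep <- !(neurons == "c" & counts == 2)
  fit2 <- spikeDffRegression(counts[keep], amps[keep], neurons[keep])
  expect_identical(fit2$excludedNeurons, "c")
})

test_that("regression stays near-perfect under mild amplitude noise", {
  set.seed(10)
  counts <- rep(1:5, each = 40)
  neurons <- rep(sprintf("n%02d", 1:10), 20)
  gain <- runif(10, 3, 8)[match(neurons, sprintf("n%02d", 1:10))]
  amps <- gain * counts * (1 + rnorm(length(counts), sd = 0.05))
  fit <- spikeDffRegression(counts, amps, neurons)
  expect_gte(fit$r2, 0.99)
})

test_that("bulk episode rate matches the generator and scales linearly", {
  rateOf <- function(er, seed) {
    cts <- synthCalciumPopulation(nNeurons = 12, durationS = 300,
                                  episodeRate = er, traceSeed = seed)
    bulk <- colSums(traces(cts))
    episodeRate(bulk - rollingBaseline(bulk, frameRate(cts)),
                frameRate(cts))$rate
  }
  r15 <- rateOf(0.15, 70)
  expect_lt(abs(r15 - 0.15), 3 * sqrt(45) / 300)  # within 3 SE of the target
  r30 <- rateOf(0.30, 71)
  expect_equal(r30 / r15, 2, tolerance = 0.35)

  expect_equal(episodeRate(rep(0, 2000), 21.7)$rate, 0)
})

test_that("segment stability is 1 for frozen dynamics and ~0 for independent structure", {
  set.seed(11)
  seg <- matrix(rnorm(6 * 200), nrow = 6)
  cts <- CalciumTraceSet(cbind(seg, seg), frameRate = 1)
  st <- segmentStabilityR2(cts, segmentS = 200)
  expect_equal(st@r2, 1, tolerance = 1e-9)

  # independent random CC vectors: R2 stays near the null expectation
  r2null <- vapply(1:20, function(i) {
    a <- rnorm(100); b <- rnorm(100)
    summary(lm(b ~ a))$r.squared
  }, numeric(1))
  expect_lt(mean(r2null), 0.05)
})

test_that("stability breaks across an iem-like condition switch but not within condition", {
  res <- vapply(1:6, function(s) {
    b <- synthCalciumPopulation(nNeurons = 16, durationS = 240,
                                condition = "baseline", couplingSeed = s,
                                traceSeed = 200 + s)
    i <- synthCalciumPopulation(nNeurons = 16, durationS = 240,
                                condition = "iem_like", couplingSeed = s,
                                traceSeed = 300 + s)
    cts <- CalciumTraceSet(cbind(traces(b), traces(i)), frameRate = 21.7)
    st <- segmentStabilityR2(cts, 120)
    c(within = mean(st@r2[c(1, 3)]), across = st@r2[2])
  }, numeric(2))
  expect_gt(mean(res["within", ] - res["across", ]), 0)
  expect_gte(sum(res["within", ] > res["across", ]), 5)
})

test_that("noise-only traces stay almost free of spurious peaks at the default threshold", {
  cts <- synthCalciumNoise(nTraces = 4, durationS = 320, seed = 12)
  tr <- traces(cts)
  frac <- vapply(seq_len(nrow(tr)), function(i) {
    dff <- tr[i, ] - rollingBaseline(tr[i, ], frameRate(cts))
    nrow(detectCaPeaks(dff)) / ncol(tr) * 100
  }, numeric(1))
  expect_lt(mean(frac), 0.5)
})
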