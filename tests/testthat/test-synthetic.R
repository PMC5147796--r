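# Synthetic-data generators: ground truth, determinism, target statistics.

test_that("discrete power-law sampler matches its PMF empirically", {
  s <- sampleDiscretePowerLaw(-1.5, 2, 2e5, seed = 4)
  p1 <- mean(s == 1)
  expect_equal(p1, 0.73880, tolerance = 0.01)

  u <- sampleDiscretePowerLaw(0, 4, 2e5, seed = 5)
  expect_equal(as.numeric(table(u)) / 2e5, rep(0.25, 4), tolerance = 0.02)

  # total-variation convergence at large n
  s3 <- sampleDiscretePowerLaw(-1.5, 8, 1e6, seed = 6)
  emp <- tabulate(s3, 8) / 1e6
  tv <- 0.5 * sum(abs(emp - discretePowerLawPmf(-1.5, 8)))
  expect_lt(tv, 0.01)
})

test_that("generators are bit-reproducible under fixed seeds", {
  expect_identical(sampleDiscretePowerLaw(-1.5, 32, 1000, seed = 3),
                   sampleDiscretePowerLaw(-1.5, 32, 1000, seed = 3))
  r1 <- simulateBranchingAvalanches(nUnits = 8, nBins = 5000, seed = 11)
  r2 <- simulateBranchingAvalanches(nUnits = 8, nBins = 5000, seed = 11)
  expect_identical(events(r1), events(r2))
  c1 <- synthCalciumPopulation(nNeurons = 4, durationS = 20, traceSeed = 9)
  c2 <- synthCalciumPopulation(nNeurons = 4, durationS = 20, traceSeed = 9)
  expect_identical(traces(c1), traces(c2))
  m1 <- synthMovementTrace(c(1, 2), durationS = 5, seed = 2)
  m2 <- synthMovementTrace(c(1, 2), durationS = 5, seed = 2)
  expect_identical(samples(m1), samples(m2))
})

test_that("zero branching yields only isolated unit-size clusters", {
  r <- simulateBranchingAvalanches(nUnits = 16, sigmaBranch = 0,
                                   driveRate = 5e-4, nBins = 5e4, seed = 8)
  cl <- extractClusters(binRaster(r, 4))
  # sizes concentrated at 1: no propagation, rare coincidences only
  expect_gt(mean(cl$sizeDiscrete == 1), 0.95)
})

test_that("mean cluster size increases with the branching parameter", {
  meanSize <- vapply(c(0, 0.5, 1), function(sig) {
    r <- simulateBranchingAvalanches(nUnits = 16, sigmaBranch = sig,
                                     driveRate = 1e-3, nBins = 4e4, seed = 300)
    mean(extractClusters(binRaster(r, 4))$sizeDiscrete)
  }, numeric(1))
  expect_true(all(diff(meanSize) > 0))
})

test_that("branching parameter above the array size is rejected", {
  expect_error(simulateBranchingAvalanches(nUnits = 8, sigmaBranch = 9),
               "exceed")
})

test_that("noiseless LFP synthesis embeds exactly recoverable events", {
  r <- EventRaster(c(0.5, 1.5, 2.5, 3.5), c(1, 2, 1, 2),
                   c(-40, -50, -45, -60), duration = 4, nChannels = 2)
  lfp <- synthLfpFromRaster(r, samplingRate = 1000, noiseSd = 0, seed = 1)
  det <- detectLfpEvents(lfp, z = -4.5,
                         sds = c(ch1 = 1, ch2 = 1))  # unit SD: threshold -4.5 uV
  ev <- events(det)
  expect_equal(nrow(ev), 4)
  expect_equal(ev$time, events(r)$time, tolerance = 2e-3)
  expect_equal(sort(ev$amplitude), sort(events(r)$amplitude), tolerance = 0.5)
})

test_that("empty raster synthesizes pure noise", {
  r <- EventRaster(numeric(0), integer(0), numeric(0), duration = 2, nChannels = 2)
  lfp <- synthLfpFromRaster(r, samplingRate = 500, noiseSd = 1, seed = 3)
  expect_equal(dim(samples(lfp)), c(2, 1000))
  expect_lt(max(abs(samples(lfp))), 6)  # no embedded deflection
})

test_that("detector recall is high on well-separated embedded events", {
  set.seed(31)
  times <- seq(0.5, 59.5, by = 0.5)
  r <- EventRaster(times, sample(1:4, length(times), TRUE),
                   -rlnorm(length(times), log(30), 0.35),
                   duration = 60, nChannels = 4)
  lfp <- synthLfpFromRaster(r, samplingRate = 1000, noiseSd = 3, seed = 32)
  det <- detectLfpEvents(lfp, z = -4.5, sds = rep(3, 4))  # noise-floor SD
  gt <- events(r); d <- events(det)
  recall <- mean(vapply(seq_len(nrow(gt)), function(i) {
    any(d$channel == gt$channel[i] & abs(d$time - gt$time[i]) < 0.01)
  }, logical(1)))
  precision <- mean(vapply(seq_len(nrow(d)), function(i) {
    any(gt$channel == d$channel[i] & abs(gt$time - d$time[i]) < 0.01)
  }, logical(1)))
  expect_gte(recall, 0.95)
  expect_gte(precision, 0.95)
})

test_that("calcium generator hits the configured episode rate and linearity", {
  cts <- synthCalciumPopulation(nNeurons = 10, durationS = 300,
                                episodeRate = 0.15, traceSeed = 60)
  nEp <- length(metadata(cts)$episodeTimes)
  # Poisson count around 45 at rate 0.15/s over 300 s
  expect_lt(abs(nEp - 45), 3 * sqrt(45))

  # noiseless single neuron: peak dF/F = ampPerSpike x spikes
  cts0 <- synthCalciumPopulation(nNeurons = 2, durationS = 60, ampPerSpike = 5,
                                 noiseSd = 0, driftAmp = 0, traceSeed = 61)
  sp <- metadata(cts0)$spikes
  k <- which(sp[1, ] > 0)[1]
  skip_if(is.na(k))
  fr <- round(metadata(cts0)$episodeTimes[k] * frameRate(cts0)) + 1L
  expect_equal(max(traces(cts0)[1, fr:(fr + 2)]), 5 * sp[1, k], tolerance = 0.3)
})

test_that("condition presets order amplitude and correlation as intended", {
  base <- synthCalciumPopulation(condition = "baseline", couplingSeed = 7, traceSeed = 21)
  ptx <- synthCalciumPopulation(condition = "ptx_like", couplingSeed = 7, traceSeed = 21)
  mb <- meanPairwiseCC(ccMatrix(base))
  mp <- meanPairwiseCC(ccMatrix(ptx))
  expect_gt(mp, mb)
  ampOf <- function(cts) {
    tr <- traces(cts)
    mean(unlist(lapply(seq_len(nrow(tr)), function(i) {
      detectCaPeaks(tr[i, ] - rollingBaseline(tr[i, ], frameRate(cts)))$amplitude
    })))
  }
  expect_gt(ampOf(ptx), ampOf(base))
})

test_that("iem-like preset preserves mean CC while decorrelating the pair structure", {
  diffs <- numeric(0); r2s <- numeric(0)
  for (s in 1:4) {
    base <- synthCalciumPopulation(condition = "baseline", couplingSeed = s,
                                   traceSeed = 500 + s)
    iem <- synthCalciumPopulation(condition = "iem_like", couplingSeed = s,
                                  traceSeed = 500 + s)
    vb <- ccValues(ccMatrix(base)); vi <- ccValues(ccMatrix(iem))
    a <- vb[upper.tri(vb)]; b <- vi[upper.tri(vi)]
    diffs <- c(diffs, abs(mean(a) - mean(b)))
    r2s <- c(r2s, summary(lm(b ~ a))$r.squared)
  }
  expect_true(all(diffs < 0.02))
  expect_true(all(r2s < 0.3))
})

test_that("movement trace embeds bursts detectable at 2 SD and a clean noise floor", {
  mv <- synthMovementTrace(seq(5, 50, by = 5), durationS = 60, fps = 40,
                           noiseSd = 0.002, seed = 3)
  det <- detectMovements(mv, z = 2)
  expect_equal(nrow(det$events), 10)

  # no bursts: threshold exceedances behave like the Gaussian tail
  mv0 <- synthMovementTrace(numeric(0), durationS = 500, fps = 40,
                            noiseSd = 0.02, seed = 4)
  det0 <- detectMovements(mv0, z = 3)
  fracAbove <- mean(samples(mv0) > det0$threshold)
  expect_lt(fracAbove, 3 * pnorm(-3))  # on the order of the tail probability
})
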