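#' @include AllClasses.R utils.R
NULL

#' Sample from a finite-support discrete power law
#'
#' Draws i.i.d. sizes from `p_alpha(s) = s^alpha / sum_{x=1..N} x^alpha` on
#' support `1..nSupport` by inverse-CDF lookup. This is the generating model
#' whose exponent the avalanche fitters recover.
#'
#' @param alpha exponent (< 0 for avalanche-like distributions; 0 gives the
#'   uniform distribution).
#' @param nSupport support size N (>= 2).
#' @param nSamples number of draws.
#' @param seed RNG seed (bit-reproducible output).
#' @return Integer vector of sizes in `1..nSupport`.
#' @examples
#' s <- sampleDiscretePowerLaw(-1.5, 32, 1000, seed = 1)
#' table(s)[1:5]
#' @export
sampleDiscretePowerLaw <- function(alpha, nSupport, nSamples, seed = 1) {
  assertScalar(alpha, "alpha")
  if (nSupport < 2) stop("'nSupport' must be >= 2", call. = FALSE)
  assertScalar(nSamples, "nSamples", lower = 1)
  pmf <- discretePowerLawPmf(alpha, nSupport)
  cdf <- cumsum(pmf)
  withSeed(seed, {
    u <- runif(nSamples)
    findInterval(u, cdf, left.open = TRUE) + 1L
  })
}

#' Simulate avalanches with a discrete-time branching process
#'
#' Runs a stochastic branching process on `nUnits` electrodes/units: at every
#' bin each unit activates spontaneously with probability `driveRate`, and
#' each unit active at bin t activates a Poisson(`sigmaBranch`) number of
#' uniformly chosen units (without replacement, truncated at `nUnits`) at bin
#' t + 1. At the critical branching parameter `sigmaBranch = 1` the cascade
#' (cluster) size distribution follows a power law with exponent close to
#' -1.5 up to the system-size cut-off, the defining signature of neuronal
#' avalanches. Events carry negative lognormal amplitudes so continuous (uV)
#' size distributions are nontrivial.
#'
#' @param nUnits number of units/electrodes (>= 2).
#' @param sigmaBranch branching parameter: expected offspring per active unit
#'   (must not exceed `nUnits`); 1 is critical.
#' @param driveRate per-unit spontaneous activation probability per bin
#'   (in [0, 1)).
#' @param nBins simulation length in bins.
#' @param binMs bin duration (ms).
#' @param seed RNG seed.
#' @param ampMeanLog,ampSdLog lognormal parameters of |amplitude| (uV).
#' @return An [EventRaster-class]; event times at bin centres.
#' @examples
#' r <- simulateBranchingAvalanches(nUnits = 8, sigmaBranch = 1,
#'                                  driveRate = 5e-3, nBins = 2000, seed = 7)
#' r
#' @export
simulateBranchingAvalanches <- function(nUnits = 32, sigmaBranch = 1,
                                        driveRate = 1e-3, nBins = 1e5,
                                        binMs = 4, seed = 1,
                                        ampMeanLog = log(30), ampSdLog = 0.35) {
  if (nUnits < 2) stop("'nUnits' must be >= 2", call. = FALSE)
  assertScalar(sigmaBranch, "sigmaBranch", lower = 0)
  if (sigmaBranch > nUnits) {
    stop("'sigmaBranch' exceeds 'nUnits': expected offspring cannot exceed the array size",
         call. = FALSE)
  }
  assertScalar(driveRate, "driveRate", lower = 0, upper = 1, strictUpper = TRUE)
  assertScalar(nBins, "nBins", lower = 1)
  assertScalar(binMs, "binMs", lower = 0, strictLower = TRUE)
  nUnits <- as.integer(nUnits)
  nBins <- as.integer(nBins)

  res <- withSeed(seed, {
    spont <- rbinom(nBins, nUnits, driveRate)
    spontBins <- which(spont > 0L)
    binsL <- vector("list", 256L)
    chsL <- vector("list", 256L)
    k <- 0L
    active <- integer(0)
    ptr <- 1L
    t <- if (length(spontBins)) spontBins[1L] else nBins + 1L
    while (t <= nBins) {
      if (ptr <= length(spontBins) && spontBins[ptr] == t) {
        active <- union(active, sample.int(nUnits, spont[t]))
        ptr <- ptr + 1L
      }
      if (length(active)) {
        k <- k + 1L
        if (k > length(binsL)) {   # grow storage geometrically
          length(binsL) <- 2L * length(binsL)
          length(chsL) <- 2L * length(chsL)
        }
        binsL[[k]] <- rep.int(t, length(active))
        chsL[[k]] <- active
        nOff <- pmin(rpois(length(active), sigmaBranch), nUnits)
        nOff <- nOff[nOff > 0L]
        active <- if (length(nOff)) {
          unique(unlist(lapply(nOff, sample.int, n = nUnits), use.names = FALSE))
        } else integer(0)
      }
      t <- if (length(active)) t + 1L
           else if (ptr <= length(spontBins)) spontBins[ptr]
           else nBins + 1L
    }
    bins <- unlist(binsL[seq_len(k)], use.names = FALSE)
    chs <- unlist(chsL[seq_len(k)], use.names = FALSE)
    amps <- -rlnorm(length(bins), ampMeanLog, ampSdLog)
    list(bins = bins, chs = chs, amps = amps)
  })

  durationS <- nBins * binMs / 1000
  if (!length(res$bins)) {
    return(EventRaster(numeric(0), integer(0), numeric(0),
                       duration = durationS, nChannels = nUnits))
  }
  times <- (res$bins - 0.5) * binMs / 1000   # bin centres
  EventRaster(times, res$chs, res$amps, duration = durationS,
              nChannels = nUnits)
}

# Stereotyped negative deflection used to embed events into continuous traces:
# a smooth unit-depth Gaussian trough of given full width.
deflectionKernel <- function(samplingRate, widthMs = 20) {
  halfW <- widthMs / 2000 * samplingRate
  idx <- seq(-ceiling(3 * halfW / 2), ceiling(3 * halfW / 2))
  -exp(-(idx / (halfW / 2))^2 / 2)
}

#' Synthesize LFP-like traces from an event raster
#'
#' Convolves a stereotyped negative (or positive) deflection at each event
#' time, scaled by the event amplitude, and adds white Gaussian noise. The
#' embedded ground-truth event times are kept in the result's attributes so
#' detector recall/precision can be measured exactly.
#'
#' @param raster an [EventRaster-class] with signed amplitudes.
#' @param samplingRate output sampling rate (Hz).
#' @param noiseSd additive noise SD (uV).
#' @param kernelWidthMs full width of the deflection (ms).
#' @param seed RNG seed for the noise.
#' @return A [TimeSeriesRecording-class]; `attr(, "groundTruth")` is the
#'   event table used for embedding.
#' @export
synthLfpFromRaster <- function(raster, samplingRate = 1000, noiseSd = 3,
                               kernelWidthMs = 20, seed = 1) {
  stopifnot(is(raster, "EventRaster"))
  assertScalar(noiseSd, "noiseSd", lower = 0)
  nSamp <- ceiling(duration(raster) * samplingRate)
  nCh <- nChannels(raster)
  kern <- deflectionKernel(samplingRate, kernelWidthMs)
  halfK <- (length(kern) - 1L) %/% 2L
  ev <- events(raster)
  mat <- withSeed(seed, matrix(rnorm(nCh * nSamp, sd = noiseSd), nrow = nCh))
  if (nrow(ev)) {
    centre <- pmin(pmax(round(ev$time * samplingRate) + 1L, 1L), nSamp)
    amp <- ifelse(is.na(ev$amplitude), -1, ev$amplitude)
    for (i in seq_len(nrow(ev))) {
      lo <- centre[i] - halfK
      hi <- centre[i] + halfK
      kLo <- max(1L, 1L + (1L - lo))
      kHi <- length(kern) - max(0L, hi - nSamp)
      lo <- max(1L, lo); hi <- min(nSamp, hi)
      seg <- kLo:kHi
      # kern is a unit-depth trough; -amp flips it for positive events
      mat[ev$channel[i], lo:hi] <- mat[ev$channel[i], lo:hi] - amp[i] * kern[seg]
    }
  }
  out <- TimeSeriesRecording(mat, samplingRate = samplingRate)
  attr(out, "groundTruth") <- ev
  out
}

calciumPresets <- list(
  baseline = list(pHi = 0.8, pLo = 0.15, spikeMean = 1),
  ptx_like = list(pHi = 0.95, pLo = 0.6, spikeMean = 3),
  iem_like = list(pHi = 0.8, pLo = 0.15, spikeMean = 1)
)

#' Synthesize a striatal calcium-imaging population
#'
#' Generates per-neuron dF/F traces driven by population episodes arriving as
#' a Poisson process at `episodeRate`. Each episode recruits one of
#' `nFactors` overlapping assemblies; member neurons of the active assembly
#' fire with high probability, non-members with low probability, producing a
#' heterogeneous pairwise-correlation structure. Spike counts are converted
#' linearly to dF/F (amplitude `ampPerSpike` % per spike) and convolved with a
#' single-exponential indicator decay, then slow baseline drift and white
#' noise are added.
#'
#' Condition presets: `"baseline"` is the low-correlation resting regime;
#' `"ptx_like"` raises participation and spike counts (higher amplitudes and
#' higher pairwise CC); `"iem_like"` permutes neuron identities of an
#' otherwise baseline-like spike matrix (permutation drawn from
#' `couplingSeed`), preserving the mean pairwise CC while reorganising which
#' pairs are coupled.
#'
#' @param nNeurons number of neurons.
#' @param durationS recording length (s).
#' @param frameRate frames per second (default 21.7).
#' @param episodeRate population-episode rate (s^-1, default 0.15).
#' @param ampPerSpike dF/F % per spike (default 5).
#' @param noiseSd additive noise SD (dF/F %).
#' @param condition one of "baseline", "ptx_like", "iem_like".
#' @param couplingSeed seed for the assembly structure (and the iem
#'   permutation).
#' @param traceSeed seed for episode times, spikes, drift and noise.
#' @param tauDecayS indicator decay time constant (s, default 0.5).
#' @param nFactors number of assemblies.
#' @param driftAmp amplitude of the slow baseline drift (dF/F %).
#' @return A [CalciumTraceSet-class]; `metadata()` holds ground truth:
#'   `episodeTimes`, `spikes` (neurons x episodes), `factors`, `condition`,
#'   and for iem_like the `permutation`.
#' @export
synthCalciumPopulation <- function(nNeurons = 20, durationS = 300,
                                   frameRate = 21.7, episodeRate = 0.15,
                                   ampPerSpike = 5, noiseSd = 1,
                                   condition = c("baseline", "ptx_like", "iem_like"),
                                   couplingSeed = 11, traceSeed = 42,
                                   tauDecayS = 0.5, nFactors = 4,
                                   driftAmp = 0.8) {
  condition <- match.arg(condition)
  assertScalar(episodeRate, "episodeRate", lower = 0, strictLower = TRUE)
  assertScalar(ampPerSpike, "ampPerSpike", lower = 0, strictLower = TRUE)
  assertScalar(noiseSd, "noiseSd", lower = 0)
  preset <- calciumPresets[[condition]]

  coupling <- withSeed(couplingSeed, {
    factors <- sample(rep_len(seq_len(nFactors), nNeurons))
    perm <- sample.int(nNeurons)
    list(factors = factors, perm = perm)
  })

  nFrames <- round(durationS * frameRate)
  out <- withSeed(traceSeed, {
    nEp <- rpois(1, episodeRate * durationS)
    epTimes <- sort(runif(nEp, 0, durationS))
    epFactor <- if (nEp) sample.int(nFactors, nEp, replace = TRUE) else integer(0)
    spikes <- matrix(0L, nrow = nNeurons, ncol = nEp)
    for (k in seq_len(nEp)) {
      pPart <- ifelse(coupling$factors == epFactor[k], preset$pHi, preset$pLo)
      part <- runif(nNeurons) < pPart
      spikes[part, k] <- 1L + rpois(sum(part), preset$spikeMean - 1)
    }
    if (condition == "iem_like") spikes <- spikes[coupling$perm, , drop = FALSE]
    # exponential indicator kernel at frame resolution
    kern <- exp(-(0:ceiling(5 * tauDecayS * frameRate)) / (tauDecayS * frameRate))
    tr <- matrix(0, nrow = nNeurons, ncol = nFrames)
    epFrame <- pmin(pmax(round(epTimes * frameRate) + 1L, 1L), nFrames)
    for (k in seq_len(nEp)) {
      active <- which(spikes[, k] > 0L)
      if (!length(active)) next
      idx <- epFrame[k]:min(nFrames, epFrame[k] + length(kern) - 1L)
      kk <- kern[seq_along(idx)]
      tr[active, idx] <- tr[active, idx] +
        (ampPerSpike * spikes[active, k]) %o% kk
    }
    list(tr = tr, epTimes = epTimes, epFactor = epFactor, spikes = spikes)
  })
  # drift and noise come from a condition-specific stream: separate
  # recordings never share measurement noise, and a shared stream would add
  # an identical pairwise component across condition presets
  out$tr <- withSeed(subSeed(traceSeed, paste0("noise_", condition)), {
    tvec <- seq_len(nFrames) / frameRate
    tr <- out$tr
    for (i in seq_len(nNeurons)) {
      drift <- driftAmp * sin(2 * pi * tvec / runif(1, 60, 150) + runif(1, 0, 2 * pi))
      tr[i, ] <- tr[i, ] + drift + rnorm(nFrames, sd = noiseSd)
    }
    tr
  })

  meta <- list(episodeTimes = out$epTimes, spikes = out$spikes,
               episodeFactors = out$epFactor, factors = coupling$factors,
               condition = condition, ampPerSpike = ampPerSpike,
               episodeRate = episodeRate)
  if (condition == "iem_like") meta$permutation <- coupling$perm
  CalciumTraceSet(out$tr, frameRate = frameRate, metadata = meta)
}

#' Synthesize event-free calcium noise traces
#'
#' The noise model of [synthCalciumPopulation()] without any population
#' episode: slow sinusoidal baseline drift plus white Gaussian noise. Used to
#' measure the spurious-detection rate of the transient detector on traces
#' that are guaranteed event-free.
#'
#' @param nTraces number of traces.
#' @param durationS trace length (s).
#' @param frameRate frames per second.
#' @param noiseSd white-noise SD (dF/F %).
#' @param driftAmp slow-drift amplitude (dF/F %).
#' @param seed RNG seed.
#' @return A [CalciumTraceSet-class] with zero embedded transients.
#' @export
synthCalciumNoise <- function(nTraces = 8, durationS = 320, frameRate = 21.7,
                              noiseSd = 1, driftAmp = 0.8, seed = 1) {
  nFrames <- round(durationS * frameRate)
  tr <- withSeed(seed, {
    tvec <- seq_len(nFrames) / frameRate
    t(vapply(seq_len(nTraces), function(i) {
      driftAmp * sin(2 * pi * tvec / runif(1, 60, 150) + runif(1, 0, 2 * pi)) +
        rnorm(nFrames, sd = noiseSd)
    }, numeric(nFrames)))
  })
  CalciumTraceSet(tr, frameRate = frameRate,
                  metadata = list(condition = "noise_only"))
}

#' Synthesize a movement signal with known bursts
#'
#' Builds a 1-minus-frame-correlation-like trace: Gaussian noise around a
#' small positive level, with a stereotyped transient excursion at each burst
#' time (plus an optional coupling lag). Ground-truth burst times are kept in
#' the attributes.
#'
#' @param burstTimes burst onset times (s); may be empty.
#' @param durationS trace length (s).
#' @param fps frames per second.
#' @param couplingLagS lag between bursts and movement excursions (s).
#' @param noiseSd noise SD of the trace.
#' @param burstAmp excursion amplitude.
#' @param burstWidthS excursion width (s).
#' @param seed RNG seed.
#' @return A [MovementSignal-class]; `attr(, "groundTruth")` holds the burst
#'   times actually embedded.
#' @export
synthMovementTrace <- function(burstTimes, durationS, fps = 40,
                               couplingLagS = 0, noiseSd = 0.02,
                               burstAmp = 0.5, burstWidthS = 0.25, seed = 1) {
  assertScalar(fps, "fps", lower = 0, strictLower = TRUE)
  assertScalar(durationS, "durationS", lower = 0, strictLower = TRUE)
  n <- round(durationS * fps)
  vals <- withSeed(seed, 0.05 + rnorm(n, sd = noiseSd))
  wFr <- max(3L, round(burstWidthS * fps))
  bump <- burstAmp * sin(seq(0, pi, length.out = wFr))^2
  embedded <- numeric(0)
  for (bt in burstTimes) {
    at <- round((bt + couplingLagS) * fps) + 1L
    if (at < 1L || at > n) next
    idx <- at:min(n, at + wFr - 1L)
    vals[idx] <- vals[idx] + bump[seq_along(idx)]
    embedded <- c(embedded, bt + couplingLagS)
  }
  out <- new("MovementSignal", values = vals, fps = fps, roi = "synthetic")
  attr(out, "groundTruth") <- embedded
  out
}
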