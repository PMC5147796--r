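#' @include AllClasses.R io.R
NULL

runConfigDefaults <- list(
  seed = 1,
  out_dir = NULL,
  # branching / avalanche stage
  n_units = 32, sigma_branch = 1, drive_rate = 1e-3, n_bins = 2e5,
  bin_ms = 4, support_n = 32, reference_alpha = -1.5,
  # event detection
  lfp_band_hz = c(1, 50), z_nlfp = -2.5, z_plfp = 2.5, mua_rule = "sd",
  # correlation
  cc_bin_ms = 4, cc_max_lag_ms = 0, n_shuffles = 10,
  # calcium stage
  calcium = TRUE, ca_n_neurons = 16, ca_duration_s = 240,
  ca_frame_rate = 21.7, ca_episode_rate = 0.15, ca_amp_per_spike = 5,
  ca_noise_sd = 1, ca_conditions = c("baseline", "ptx_like", "iem_like"),
  segment_s = 120,
  # movement stage
  movement = TRUE, mv_fps = 40, mv_duration_s = 60, mv_n_bursts = 10,
  mv_z = 2.5
)

#' Build and validate a run configuration
#'
#' Merges user settings over the documented defaults and validates ranges.
#' Unknown keys are rejected; out-of-range values name the offending key.
#'
#' @param ... configuration keys (see `critstate:::runConfigDefaults` for the
#'   full set and defaults).
#' @return A validated named list of class `RunConfig`.
#' @export
makeRunConfig <- function(...) {
  user <- list(...)
  unknown <- setdiff(names(user), names(runConfigDefaults))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- runConfigDefaults
  cfg[names(user)] <- user
  checks <- list(
    n_units = cfg$n_units >= 2,
    sigma_branch = cfg$sigma_branch >= 0 && cfg$sigma_branch <= cfg$n_units,
    drive_rate = cfg$drive_rate >= 0 && cfg$drive_rate < 1,
    n_bins = cfg$n_bins >= 1,
    bin_ms = cfg$bin_ms > 0,
    support_n = cfg$support_n >= 2,
    z_nlfp = cfg$z_nlfp != 0,
    z_plfp = cfg$z_plfp != 0,
    cc_bin_ms = cfg$cc_bin_ms > 0,
    n_shuffles = cfg$n_shuffles >= 1,
    ca_episode_rate = cfg$ca_episode_rate > 0,
    ca_amp_per_spike = cfg$ca_amp_per_spike > 0,
    segment_s = cfg$segment_s > 0,
    mv_fps = cfg$mv_fps > 0,
    mv_z = cfg$mv_z > 0
  )
  bad <- names(checks)[!vapply(checks, isTRUE, logical(1))]
  if (length(bad)) {
    stop("invalid config value(s) for key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  class(cfg) <- c("RunConfig", "list")
  cfg
}

#' Run the full synthetic analysis pipeline
#'
#' Chains the stages end-to-end on synthetic inputs with known ground truth:
#' branching-process simulation, binning, cluster extraction, power-law /
#' exponential MLE with LLR comparison and KS distance against the reference
#' exponent; shuffle-corrected pairwise correlations of the event raster;
#' the calcium pipeline per condition preset (episode rate, mean pairwise
#' CC, transient amplitudes, segment-stability R^2); and movement extraction.
#' The resolved configuration (including all seeds) is embedded in the
#' summary so a rerun is byte-identical.
#'
#' @param config a `RunConfig` from [makeRunConfig()] (or arguments for it).
#' @return Invisibly, the summary list; written as JSON (plus per-stage TSV
#'   tables) to `config$out_dir` when set.
#' @export
runPipeline <- function(config = makeRunConfig()) {
  if (!inherits(config, "RunConfig")) {
    stop("'config' must come from makeRunConfig()", call. = FALSE)
  }
  seed <- config$seed
  summary <- list(config = unclass(config))

  ## avalanche branch
  raster <- simulateBranchingAvalanches(
    nUnits = config$n_units, sigmaBranch = config$sigma_branch,
    driveRate = config$drive_rate, nBins = config$n_bins,
    binMs = config$bin_ms, seed = subSeed(seed, "branching"))
  binned <- binRaster(raster, config$bin_ms)
  clusters <- extractClusters(binned)
  if (!nrow(clusters)) stop("stage avalanche_detection: no clusters extracted",
                            call. = FALSE)
  dist <- sizeDistribution(clusters, supportN = config$support_n)
  fitSizes <- supportSizes(dist)
  pl <- fitPowerLawMLE(fitSizes, config$support_n)
  llr <- llrTest(fitSizes, config$support_n)
  ks <- ksDistance(dist, config$reference_alpha)
  cstats <- clusterStatistics(clusters, duration(raster), config$bin_ms)
  summary$avalanche <- list(
    n_events = nrow(events(raster)),
    n_clusters = nrow(clusters),
    cluster_rate_hz = cstats$rate,
    mean_duration_ms = cstats$meanDurationMs,
    alpha_hat = alphaHat(pl),
    lambda_hat = lambdaHat(llr@exponentialFit),
    llr = llr@llr, llr_p = llr@pValue, favored = llr@favored,
    d_ks = ks@dKs,
    n_above_cutoff = attr(fitSizes, "nAboveCutoff")
  )

  ## event-raster correlations (shuffle-corrected, tau = 0)
  cm <- ccMatrix(binned, source = "nlfp", corrected = TRUE,
                 nShuffles = config$n_shuffles, seed = subSeed(seed, "cc"))
  summary$correlation <- list(mean_pairwise_cc = tryCatch(
    meanPairwiseCC(cm), error = function(e) NA_real_))

  ## calcium branch
  if (isTRUE(config$calcium)) {
    ca <- list()
    for (cond in config$ca_conditions) {
      cts <- synthCalciumPopulation(
        nNeurons = config$ca_n_neurons, durationS = config$ca_duration_s,
        frameRate = config$ca_frame_rate, episodeRate = config$ca_episode_rate,
        ampPerSpike = config$ca_amp_per_spike, noiseSd = config$ca_noise_sd,
        condition = cond, couplingSeed = subSeed(seed, "coupling"),
        traceSeed = subSeed(seed, paste0("traces_", cond)))
      tr <- traces(cts)
      bulk <- colSums(tr)
      er <- episodeRate(bulk - rollingBaseline(bulk, frameRate(cts)),
                        frameRate(cts))
      cmDff <- ccMatrix(cts)
      amps <- unlist(lapply(seq_len(nrow(tr)), function(i) {
        detectCaPeaks(tr[i, ] - rollingBaseline(tr[i, ], frameRate(cts)))$amplitude
      }))
      st <- tryCatch(segmentStabilityR2(cts, config$segment_s),
                     error = function(e) NULL)
      ca[[cond]] <- list(
        episode_rate_hz = er$rate,
        mean_pairwise_cc = meanPairwiseCC(cmDff),
        mean_peak_amplitude = if (length(amps)) mean(amps) else NA_real_,
        stability_r2 = if (is.null(st)) NA_real_ else mean(st@r2, na.rm = TRUE)
      )
    }
    summary$calcium <- ca
  }

  ## movement branch
  if (isTRUE(config$movement)) {
    bursts <- withSeed(subSeed(seed, "bursts"),
                       sort(runif(config$mv_n_bursts, 2,
                                  config$mv_duration_s - 2)))
    mv <- synthMovementTrace(bursts, durationS = config$mv_duration_s,
                             fps = config$mv_fps,
                             seed = subSeed(seed, "movement"))
    det <- detectMovements(mv, z = config$mv_z)
    summary$movement <- list(
      n_embedded = length(attr(mv, "groundTruth")),
      n_detected = nrow(det$events),
      rate_hz = det$rate
    )
  }

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write.table(clusters, file.path(config$out_dir, "clusters.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    write.table(sizePmf(dist), file.path(config$out_dir, "size_pmf.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(summary)
}
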