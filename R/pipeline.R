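#' Pipeline configuration
#'
#' Collects every stage parameter with the protocol's canonical
#' defaults (5.81 Hz imaging, 315 s trials of 10 s motion / 5 s static,
#' classification threshold 0.6, clustering threshold 0.75 with minimum
#' cluster size 50, 2-pixel spatial mean filter) and validates ranges
#' before any stage runs.
#'
#' @param seed master seed for the simulation and any stochastic stage.
#' @param trialDuration,motionS,staticS stimulus schedule (s).
#' @param frameRateHz imaging frame rate (Hz).
#' @param behaviourRateHz tail-camera rate (Hz).
#' @param frameShape movie geometry (rows, cols) for simulation.
#' @param nPerArchetype simulated ROI counts per archetype.
#' @param classifyThreshold mean event-correlation threshold.
#' @param clusterThreshold clustering correlation threshold.
#' @param clusterMinSize minimum cluster size.
#' @param filterPx spatial mean filter size (px).
#' @param baselineMethod dF/F baseline method (see [dff()]).
#' @param noise noise parameters ([noiseParams()] / [zeroNoise()]).
#' @param bleedFactor simulated red-to-green bleed-through factor.
#' @param boutDetection named list of bout-extraction overrides
#'   (see [findBouts()]).
#' @return validated configuration list of class `"hindscopeConfig"`.
#' @export
pipelineConfig <- function(seed = 1L, trialDuration = 315, motionS = 10,
                           staticS = 5, frameRateHz = 5.81,
                           behaviourRateHz = 250,
                           frameShape = c(128L, 64L),
                           nPerArchetype = c(swim_locked = 20L,
                                             stim_on = 20L, mixed = 20L,
                                             stim_suppressed = 20L),
                           classifyThreshold = 0.6,
                           clusterThreshold = 0.75, clusterMinSize = 8L,
                           filterPx = 2L,
                           baselineMethod = "sliding_percentile",
                           noise = noiseParams(), bleedFactor = 0.15,
                           boutDetection = list()) {
  cfg <- list(seed = as.integer(seed), trialDuration = trialDuration,
              motionS = motionS, staticS = staticS,
              frameRateHz = frameRateHz, behaviourRateHz = behaviourRateHz,
              frameShape = as.integer(frameShape),
              nPerArchetype = nPerArchetype,
              classifyThreshold = classifyThreshold,
              clusterThreshold = clusterThreshold,
              clusterMinSize = as.integer(clusterMinSize),
              filterPx = as.integer(filterPx),
              baselineMethod = baselineMethod, noise = noise,
              bleedFactor = bleedFactor, boutDetection = boutDetection)
  validatePipelineConfig(cfg)
  class(cfg) <- "hindscopeConfig"
  cfg
}

#' Validate a pipeline configuration
#'
#' @param cfg configuration list.
#' @return `TRUE` invisibly; stops with a validation error otherwise.
#' @export
validatePipelineConfig <- function(cfg) {
  chk <- function(cond, msg) if (!cond) .stopf("config invalid: %s", msg)
  chk(cfg$trialDuration > 0, "trialDuration must be positive")
  chk(cfg$motionS > 0 && cfg$staticS > 0, "stimulus durations must be positive")
  chk(cfg$frameRateHz > 0, "frameRateHz must be positive")
  chk(cfg$behaviourRateHz > 0, "behaviourRateHz must be positive")
  chk(cfg$classifyThreshold >= -1 && cfg$classifyThreshold <= 1,
      "classifyThreshold must lie in [-1, 1]")
  chk(cfg$clusterThreshold >= -1 && cfg$clusterThreshold <= 1,
      "clusterThreshold must lie in [-1, 1]")
  chk(cfg$clusterMinSize >= 1L, "clusterMinSize must be >= 1")
  chk(cfg$filterPx >= 1L, "filterPx must be >= 1")
  chk(cfg$bleedFactor >= 0, "bleedFactor must be >= 0")
  chk(cfg$baselineMethod %in% c("sliding_percentile", "quiet_mean", "fixed"),
      "unknown baselineMethod")
  invisible(TRUE)
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match [pipelineConfig()] arguments.
#' @return validated configuration.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(pipelineConfig))
  bad <- setdiff(names(y), known)
  if (length(bad)) .stopf("config invalid: unknown key(s) %s",
                          paste(bad, collapse = ", "))
  if (!is.null(y$nPerArchetype)) y$nPerArchetype <- unlist(y$nPerArchetype)
  if (!is.null(y$noise)) y$noise <- do.call(noiseParams, y$noise)
  do.call(pipelineConfig, y)
}

#' Run the full analysis pipeline on a simulated experiment
#'
#' Executes every stage in order - simulate, bout extraction from the
#' tail trace, bleed-through estimation and correction, ROI trace
#' extraction, dF/F, event windows, classification, per-category
#' clustering, and pixel correlation maps - and returns all intermediate
#' products plus a manifest describing parameters, seed and stage
#' outputs. With a fixed seed the run is bit-reproducible. When
#' `outdir` is given, artifacts (bout table, classification table,
#' centroids, maps and the manifest) are also written to disk.
#'
#' @param config configuration from [pipelineConfig()].
#' @param outdir optional output directory.
#' @param larvaId identifier stored on the maps.
#' @return list with `experiment` (simulation ground truth), `bouts`,
#'   `bleedFactorHat`, `se` (a
#'   [SummarizedExperiment::SummarizedExperiment] of dF/F traces with
#'   classification in `rowData`), `classification`, `swimClusters`,
#'   `stimClusters`, `maps` (list of [CorrelationMap]), and `manifest`.
#' @export
runPipeline <- function(config = pipelineConfig(), outdir = NULL,
                        larvaId = "larva1") {
  validatePipelineConfig(config)
  exp <- simulateExperiment(
    seed = config$seed, trialDuration = config$trialDuration,
    motionS = config$motionS, staticS = config$staticS,
    frameShape = config$frameShape,
    nPerArchetype = config$nPerArchetype,
    frameRateHz = config$frameRateHz,
    behaviourRateHz = config$behaviourRateHz, noise = config$noise,
    bleedFactor = config$bleedFactor)

  bouts <- findBouts(exp$tail, config$boutDetection)

  bleedHat <- estimateBleedthrough(exp$green, exp$red)
  greenCorr <- correctBleedthrough(exp$green, exp$red, bleedHat)

  raw <- extractRoiTraces(greenCorr, exp$scene@footprints)
  dffMat <- t(apply(raw, 1L, dff, frameRateHz = config$frameRateHz,
                    method = config$baselineMethod))

  cls <- classifyRois(dffMat, bouts, exp$schedule, config$frameRateHz,
                      threshold = config$classifyThreshold)
  cls$archetype <- exp$scene@archetypes

  dur <- trialDuration(exp$schedule)
  swimSpec <- swimWindowSpec()
  stimSpec <- stimulusWindowSpec()
  swimEv <- selectEvents(bouts, swimSpec, dur)
  stimEv <- selectEvents(exp$schedule, stimSpec, dur)

  triggeredAvg <- function(rois, ev, spec) {
    t(vapply(rois, function(i)
      triggeredAverage(extractWindows(dffMat[i, ], ev, spec,
                                      config$frameRateHz)),
      numeric(round((spec@preS + spec@postS) * config$frameRateHz))))
  }
  swimRois <- which(cls$category == "swim_driven")
  stimRois <- which(cls$category == "stimulus_driven")
  swimClusters <- if (length(swimRois) >= 2L && length(swimEv) >= 1L)
    clusterTraces(triggeredAvg(swimRois, swimEv, swimSpec),
                  config$clusterThreshold, config$clusterMinSize, "swim")
  else list(clusters = list(), assignment = integer(0))
  stimClusters <- if (length(stimRois) >= 2L && length(stimEv) >= 1L)
    clusterTraces(triggeredAvg(stimRois, stimEv, stimSpec),
                  config$clusterThreshold, config$clusterMinSize, "stimulus")
  else list(clusters = list(), assignment = integer(0))

  cls$cluster <- NA_integer_
  if (length(swimClusters$clusters))
    cls$cluster[swimRois] <- swimClusters$assignment
  if (length(stimClusters$clusters))
    cls$cluster[stimRois] <- stimClusters$assignment

  maps <- list()
  for (cl in swimClusters$clusters)
    maps[[sprintf("swim_%d", cl@clusterId)]] <- clusterCorrelationMap(
      greenCorr, cl@centroid, swimEv, swimSpec, config$filterPx,
      clusterId = cl@clusterId, larvaId = larvaId)
  for (cl in stimClusters$clusters)
    maps[[sprintf("stimulus_%d", cl@clusterId)]] <- clusterCorrelationMap(
      greenCorr, cl@centroid, stimEv, stimSpec, config$filterPx,
      clusterId = cl@clusterId, larvaId = larvaId)

  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(dff = dffMat),
    rowData = S4Vectors::DataFrame(cls),
    metadata = list(frameRateHz = config$frameRateHz,
                    schedule = exp$schedule, bouts = bouts,
                    swimEvents = swimEv, stimulusEvents = stimEv))

  manifest <- list(
    seed = config$seed,
    parameters = config[setdiff(names(config), "noise")],
    noise = config$noise,
    nBoutsDetected = nrow(bouts),
    nBoutsExcluded = sum(bouts$excluded),
    nSwimEvents = length(swimEv), nStimulusEvents = length(stimEv),
    bleedFactorHat = bleedHat,
    categoryCounts = as.list(table(cls$category)),
    nClusters = length(swimClusters$clusters) +
      length(stimClusters$clusters),
    packageVersion = as.character(utils::packageVersion("hindscope")))

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    writeBoutTable(bouts, file.path(outdir, "bouts.csv"))
    write.csv(cls, file.path(outdir, "classification.csv"),
              row.names = FALSE)
    allCl <- c(swimClusters$clusters, stimClusters$clusters)
    if (length(allCl)) {
      cent <- do.call(rbind, lapply(allCl, function(cl)
        data.frame(event_kind = cl@eventKind, cluster_id = cl@clusterId,
                   t(cl@centroid))))
      write.csv(cent, file.path(outdir, "centroids.csv"), row.names = FALSE)
    }
    for (nm in names(maps))
      writeCorrelationMapTiff(maps[[nm]],
                              file.path(outdir, paste0("map_", nm, ".tif")))
    files <- setdiff(list.files(outdir, full.names = TRUE), "manifest.json")
    manifest$fileHashes <- as.list(tools::md5sum(files))
    names(manifest$fileHashes) <- basename(files)
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  list(experiment = exp, bouts = bouts, bleedFactorHat = bleedHat,
       se = se, classification = cls, swimClusters = swimClusters,
       stimClusters = stimClusters, maps = maps, manifest = manifest)
}
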