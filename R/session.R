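# Session-level orchestration: configuration, seeding, the end-to-end
# simulate -> analyze -> report workflow, and report I/O.

#' Session configuration
#'
#' A single configuration object collecting every threshold and parameter
#' used anywhere in the pipeline, so a session is fully reproducible from
#' (config, seed). Defaults describe a desk-scale open-loop
#' electrophysiology-style session: 2-ms clock, 4-s open-loop trials
#' (1 s move-in, 2 s hold, 1 s move-out) with hold distances tiling
#' 4-40 mm, three repetitions each, constant 20 cm/s running.
#'
#' @param seed master seed; behavior, neuron and movie seeds are derived
#'   from it
#' @param coupling list(gain, dt, corridorHalfwidth, minWallDistance,
#'   trialLength)
#' @param trials list(holdDistances, repetitions, schedule, farDistance)
#' @param policy list(kind, steeringGain, noiseSd, speed)
#' @param population named counts per tuning family
#' @param analysis list(speedThreshold, binWidth, maxDistance, alpha,
#'   activeThreshold, rangeThreshold, outOfReachThreshold, minTrials)
#' @param imaging list(enabled, height, width, frameRate, nRois, roiRadius,
#'   maxShift, noiseSd)
#' @return a list of class \code{"SessionConfig"}
#' @export
sessionConfig <- function(seed = 1L,
                          coupling = list(),
                          trials = list(),
                          policy = list(),
                          population = c(unimodal = 10, monotonic_decreasing = 5,
                                         monotonic_increasing = 3, untuned = 7),
                          analysis = list(),
                          imaging = list()) {
  cfg <- list(
    seed = as.integer(seed),
    coupling = utils::modifyList(list(
      gain = 1, dt = 0.002, corridorHalfwidth = 19, minWallDistance = 4,
      trialLength = 200), coupling),
    trials = utils::modifyList(list(
      holdDistances = seq(4, 40, by = 4), repetitions = 3,
      schedule = c(1, 2, 1), farDistance = 45), trials),
    policy = utils::modifyList(list(
      kind = "ideal", steeringGain = 2, noiseSd = 0, speed = 20,
      speedSd = 0), policy),
    population = population,
    analysis = utils::modifyList(list(
      speedThreshold = 3, binWidth = 3, maxDistance = 42, alpha = 0.05,
      activeThreshold = 1.0, rangeThreshold = 0.3, outOfReachThreshold = 30,
      minTrials = 3), analysis),
    imaging = utils::modifyList(list(
      enabled = FALSE, height = 64, width = 64, frameRate = 7,
      nRois = 12, roiRadius = 4, maxShift = 3, noiseSd = 0), imaging)
  )
  stopifnot(cfg$analysis$speedThreshold > 0, cfg$analysis$binWidth > 0,
            cfg$analysis$alpha > 0, cfg$analysis$activeThreshold > 0,
            cfg$analysis$rangeThreshold > 0)
  class(cfg) <- "SessionConfig"
  cfg
}

#' Read / write a session configuration as YAML
#' @param cfg a \code{SessionConfig}
#' @param path YAML file path
#' @return \code{readSessionConfig} returns a \code{SessionConfig}
#' @export
writeSessionConfig <- function(cfg, path) {
  raw <- unclass(cfg)
  raw$population <- as.list(raw$population)  # keep names through YAML
  yaml::write_yaml(raw, path)
  invisible(path)
}

#' @rdname writeSessionConfig
#' @export
readSessionConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  sessionConfig(seed = if (is.null(raw$seed)) 1L else raw$seed,
                coupling = if (is.null(raw$coupling)) list() else raw$coupling,
                trials = if (is.null(raw$trials)) list() else raw$trials,
                policy = if (is.null(raw$policy)) list() else raw$policy,
                population = if (is.null(raw$population))
                  c(unimodal = 10, monotonic_decreasing = 5,
                    monotonic_increasing = 3, untuned = 7)
                  else unlist(raw$population),
                analysis = if (is.null(raw$analysis)) list() else raw$analysis,
                imaging = if (is.null(raw$imaging)) list() else raw$imaging)
}

# Open-loop trial list of a config: hold distances x repetitions, in a
# deterministic interleaved order.
configTrials <- function(cfg) {
  holds <- rep(cfg$trials$holdDistances, cfg$trials$repetitions)
  lapply(holds, function(h)
    corridorTrial(mode = "open_loop", openLoopDistance = h,
                  schedule = cfg$trials$schedule,
                  farDistance = cfg$trials$farDistance))
}

configCoupling <- function(cfg) {
  do.call(couplingParams, cfg$coupling)
}

configPolicy <- function(cfg) {
  do.call(trackingPolicy, cfg$policy)
}

#' Simulate the behavioral session described by a config
#' @param cfg a \code{SessionConfig}
#' @return a \code{BehaviorTimeSeries}
#' @export
simulateConfigBehavior <- function(cfg) {
  simulateSession(configTrials(cfg), configPolicy(cfg), configCoupling(cfg),
                  seed = cfg$seed)
}

#' Run the full simulate -> analyze -> report pipeline
#'
#' Simulates the behavioral session, draws a ground-truth population,
#' generates spikes, runs the spike-train analyses on every unit, optionally
#' renders and analyzes a synthetic imaging session, and aggregates
#' population statistics. Deterministic given the config seed.
#'
#' @param cfg a \code{SessionConfig}
#' @param outDir optional output directory; when given, behavior, spikes,
#'   the per-unit table and the report are written under \code{behavior/},
#'   \code{neural/}, \code{imaging/} and \code{report/}
#' @param verbose print progress and the thresholds used
#' @return a list of class \code{"PopulationReport"}: per-unit table
#'   (\code{units}), population fractions and histograms, and (when imaging
#'   is enabled) ROI classification fractions
#' @export
runPipeline <- function(cfg, outDir = NULL, verbose = FALSE) {
  stopifnot(inherits(cfg, "SessionConfig"))
  an <- cfg$analysis
  if (verbose)
    message("thresholds: speed>", an$speedThreshold, " cm/s, ",
            an$binWidth, "-mm bins to ", an$maxDistance, " mm, alpha=",
            an$alpha, ", active>", an$activeThreshold, ", range>",
            an$rangeThreshold, ", out-of-reach>", an$outOfReachThreshold,
            " mm")
  behavior <- tryCatch(simulateConfigBehavior(cfg),
                       error = function(e) stop("[behavior] ", conditionMessage(e)))
  pop <- tryCatch(
    makePopulation(cfg$population, seed = cfg$seed + 1L),
    error = function(e) stop("[neurons] ", conditionMessage(e)))

  breaks <- seq(0, an$maxDistance, by = an$binWidth)
  u <- wallDistance(behavior, "right")
  wv <- wallVelocity(behavior, "right")
  tt <- sampleTimes(behavior)

  spikes <- vector("list", length(pop))
  rows <- vector("list", length(pop))
  for (i in seq_along(pop)) {
    model <- pop[[i]]
    rate <- neuronRate(model, u, wv, runSpeed(behavior))
    sp <- generateSpikes(rate, tt, seed = cfg$seed * 100L + i)
    spikes[[i]] <- sp
    rateSeries <- binSpikeRate(sp, times = tt)
    curve <- distanceTuning(rateSeries, behavior, breaks = breaks,
                            speedThreshold = an$speedThreshold,
                            minTrials = an$minTrials,
                            baselineThreshold = an$outOfReachThreshold)
    summ <- tuningSummary(curve, alpha = an$alpha)
    peakLoc <- curve@binCenters[which.max(curve@mean)]
    rows[[i]] <- cbind(
      data.frame(unit_id = sprintf("unit%03d", i), kind = model@kind,
                 true_preferred = if (length(model@preferred))
                   model@preferred[1] else NA_real_,
                 n_spikes = length(sp), peak_distance = peakLoc),
      summ)
  }
  names(spikes) <- sprintf("unit%03d", seq_along(pop))
  units <- if (length(rows)) do.call(rbind, rows) else
    data.frame(unit_id = character(), kind = character(),
               true_preferred = numeric(), n_spikes = integer(),
               peak_distance = numeric(), baseline = numeric(),
               peak = numeric(), minimum = numeric(),
               activation = numeric(), suppression = numeric(),
               modulation = numeric(), p = numeric(), tuned = logical())

  histBreaks <- breaks
  peakHist <- graphics::hist(units$peak_distance[units$tuned],
                             breaks = histBreaks, plot = FALSE)
  modBreaks <- seq(-1, 1, by = 0.2)
  modHist <- graphics::hist(
    pmin(pmax(units$modulation[is.finite(units$modulation)], -1), 1),
    breaks = modBreaks, plot = FALSE)

  report <- list(
    nUnits = nrow(units),
    fractionTuned = if (nrow(units)) mean(units$tuned) else NA_real_,
    peakHistogram = list(breaks = peakHist$breaks, counts = peakHist$counts),
    modulationHistogram = list(breaks = modHist$breaks,
                               counts = modHist$counts),
    thresholds = an,
    seed = cfg$seed,
    units = units
  )

  if (isTRUE(cfg$imaging$enabled)) {
    report$imaging <- tryCatch(runImagingBranch(cfg, behavior, pop),
                               error = function(e) stop("[imaging] ",
                                                        conditionMessage(e)))
  }
  class(report) <- "PopulationReport"

  if (!is.null(outDir)) {
    for (d in c("behavior", "neural", "report"))
      dir.create(file.path(outDir, d), recursive = TRUE, showWarnings = FALSE)
    writeBehavior(behavior, file.path(outDir, "behavior", "behavior.csv"))
    writeSpikes(spikes, file.path(outDir, "neural", "spikes.csv"))
    utils::write.csv(units, file.path(outDir, "neural", "units.csv"),
                     row.names = FALSE)
    writeReport(report, file.path(outDir, "report"))
    jsonlite::write_json(
      list(package = "tactileVR",
           version = as.character(utils::packageVersion("tactileVR")),
           seed = cfg$seed, config = unclass(cfg)),
      file.path(outDir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  }
  report
}

# Imaging branch of the pipeline: render a synthetic movie from the first
# nRois population models, inject rigid drift, then run the full imaging
# analysis and classify each ROI.
runImagingBranch <- function(cfg, behavior, pop) {
  im <- cfg$imaging
  an <- cfg$analysis
  frameRate <- im$frameRate
  nR <- min(im$nRois, length(pop))
  dur <- max(sampleTimes(behavior))
  frameTimes <- seq(0, dur - 1 / frameRate, by = 1 / frameRate)
  nT <- length(frameTimes)

  u <- wallDistance(behavior, "right")
  wv <- wallVelocity(behavior, "right")
  tt <- sampleTimes(behavior)
  kern <- calciumKernelParams(noiseSd = im$noiseSd)
  clock <- seq(0, dur, by = 0.01)  # forward-model clock
  uC <- stats::approx(tt, u, clock, rule = 2)$y
  wvC <- stats::approx(tt, wv, clock, method = "constant", rule = 2)$y
  vC <- stats::approx(tt, runSpeed(behavior), clock, rule = 2)$y

  roiDff <- matrix(0, nT, nR)
  gtSpikes <- vector("list", nR)
  for (r in seq_len(nR)) {
    rate <- neuronRate(pop[[r]], uC, wvC, vC)
    sp <- generateSpikes(rate, clock, seed = cfg$seed * 1000L + r)
    gtSpikes[[r]] <- sp
    dffFine <- spikesToDff(sp, clock, kern)
    roiDff[, r] <- stats::approx(clock, dffFine, frameTimes, rule = 2)$y
  }
  masks <- makeRoiGrid(im$height, im$width, nR, radius = im$roiRadius,
                       margin = 2 * 8)
  rois <- roiSet(masks)
  set.seed(cfg$seed + 7L)
  shifts <- matrix(sample(seq(-im$maxShift, im$maxShift), 2 * nT,
                          replace = TRUE), nT, 2)
  shifts[1, ] <- 0L  # the first frame anchors the reference
  movie <- renderMovie(rois, roiDff, frameTimes, shifts = shifts,
                       kernel = kern, seed = cfg$seed + 8L,
                       spikes = gtSpikes)

  reg <- registerMovie(movie, reference = movie@frames[, , 1])
  dff <- roiDffTraces(reg$movie, rois)
  btsF <- downsampleToFrames(behavior, frameTimes)
  status <- character(nR)
  for (r in seq_len(nR)) {
    curve <- distanceTuning(dff[, r], btsF,
                            breaks = seq(0, an$maxDistance, by = an$binWidth),
                            speedThreshold = an$speedThreshold,
                            minTrials = an$minTrials,
                            baselineThreshold = an$outOfReachThreshold,
                            unit = "dff")
    status[r] <- classifyRoi(dff[, r], curve,
                             activeThreshold = an$activeThreshold,
                             rangeThreshold = an$rangeThreshold,
                             alpha = an$alpha)$status
  }
  counts <- table(factor(status,
                         levels = c("inactive", "active_untuned", "tuned")))
  list(nRois = nR, counts = as.list(counts),
       fractions = as.list(counts / nR),
       recoveredShifts = all(reg$shifts == movie@groundTruth$shifts),
       status = status,
       trueKind = vapply(pop[seq_len(nR)], function(m) m@kind, character(1)))
}

#' Write a population report to disk
#'
#' Machine-readable JSON (population statistics, histograms, thresholds) and
#' a CSV per-unit table.
#'
#' @param report a \code{PopulationReport}
#' @param dir output directory (created if needed)
#' @return the directory, invisibly
#' @export
writeReport <- function(report, dir) {
  stopifnot(inherits(report, "PopulationReport"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  core <- unclass(report)
  units <- core$units
  core$units <- NULL
  core$schema <- "tactileVR-report-1"
  jsonlite::write_json(core, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(units))
    utils::write.csv(units, file.path(dir, "units.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a population report written by \code{writeReport}
#' @param dir report directory
#' @return a \code{PopulationReport}
#' @export
readReport <- function(dir) {
  core <- jsonlite::read_json(file.path(dir, "report.json"),
                              simplifyVector = TRUE)
  csv <- file.path(dir, "units.csv")
  if (file.exists(csv)) core$units <- utils::read.csv(csv)
  class(core) <- "PopulationReport"
  core
}

#' @export
print.PopulationReport <- function(x, ...) {
  cat(sprintf("PopulationReport: %d units, %.1f%% tuned\n",
              x$nUnits, 100 * x$fractionTuned))
  if (!is.null(x$imaging))
    cat(sprintf("  imaging: %d ROIs, fractions %s\n", x$imaging$nRois,
                paste(sprintf("%s=%.2f", names(x$imaging$fractions),
                              unlist(x$imaging$fractions)), collapse = ", ")))
  invisible(x)
}
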