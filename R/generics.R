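# Generics, accessors and show methods for the core containers.

#' Number of samples or frames in an object
#' @param x a BehaviorTimeSeries or CalciumMovie
#' @return integer length
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname nSamples
#' @export
setMethod("nSamples", "BehaviorTimeSeries", function(x) length(x@t))

#' @rdname nSamples
#' @export
setMethod("nSamples", "CalciumMovie", function(x) dim(x@frames)[3])

#' Sample or frame times
#' @param x a BehaviorTimeSeries or CalciumMovie
#' @return numeric vector of times in seconds
#' @export
setGeneric("sampleTimes", function(x) standardGeneric("sampleTimes"))

#' @rdname sampleTimes
#' @export
setMethod("sampleTimes", "BehaviorTimeSeries", function(x) x@t)

#' @rdname sampleTimes
#' @export
setMethod("sampleTimes", "CalciumMovie", function(x) x@frameTimes)

#' Run speed of a behavioral series (cm/s)
#' @param x a BehaviorTimeSeries
#' @return numeric vector
#' @export
runSpeed <- function(x) x@v

#' Run angle of a behavioral series (degrees)
#' @param x a BehaviorTimeSeries
#' @return numeric vector
#' @export
runAngle <- function(x) x@phi

#' Snout-to-wall distance (mm)
#' @param x a BehaviorTimeSeries
#' @param side "left" or "right"
#' @return numeric vector
#' @export
wallDistance <- function(x, side = c("right", "left")) {
  side <- match.arg(side)
  if (side == "right") x@uRight else x@uLeft
}

#' Trial labels of a behavioral series
#' @param x a BehaviorTimeSeries
#' @return integer vector
#' @export
trialIds <- function(x) x@trialId

#' Signed wall velocity (mm/s)
#'
#' Discrete time derivative of the wall distance on one side, computed
#' within trial boundaries (the first sample of each trial has velocity 0,
#' so trial transitions do not create spurious wall movement). Negative
#' velocity means the wall is approaching the animal.
#'
#' @param x a BehaviorTimeSeries
#' @param side which wall, "right" (default, the conventionally
#'   contralateral wall) or "left"
#' @return numeric vector, mm/s
#' @export
wallVelocity <- function(x, side = c("right", "left")) {
  side <- match.arg(side)
  u <- wallDistance(x, side)
  n <- length(u)
  if (n < 2) return(rep(0, n))
  dt <- x@t[2] - x@t[1]
  vel <- c(0, diff(u) / dt)
  newTrial <- c(TRUE, diff(x@trialId) != 0)
  vel[newTrial] <- 0
  vel
}

#' Convert a behavioral series to a data.frame
#' @param x a BehaviorTimeSeries
#' @param ... unused
#' @return data.frame with columns t, v, phi, u_left, u_right, trial_id
#' @export
setMethod("as.data.frame", "BehaviorTimeSeries", function(x, ...) {
  data.frame(t = x@t, v = x@v, phi = x@phi, u_left = x@uLeft,
             u_right = x@uRight, trial_id = x@trialId)
})

#' Frames of a calcium movie
#' @param x a CalciumMovie
#' @return H x W x T numeric array
#' @export
movieFrames <- function(x) x@frames

#' Ground-truth annotations of a synthetic movie
#' @param x a CalciumMovie
#' @return list (empty for non-synthetic movies)
#' @export
groundTruth <- function(x) x@groundTruth

#' Bin centers of a tuning curve or pixelwise map
#' @param x a TuningCurve or PixelwiseMap
#' @return numeric vector, mm
#' @export
setGeneric("binCenters", function(x) standardGeneric("binCenters"))

#' @rdname binCenters
#' @export
setMethod("binCenters", "TuningCurve", function(x) x@binCenters)

#' @rdname binCenters
#' @export
setMethod("binCenters", "PixelwiseMap", function(x) x@binCenters)

#' Mean response per bin of a tuning curve
#' @param x a TuningCurve
#' @return numeric vector (NA for under-sampled bins)
#' @export
curveMean <- function(x) x@mean

#' Standard error per bin of a tuning curve
#' @param x a TuningCurve
#' @return numeric vector
#' @export
curveSE <- function(x) x@se

#' Out-of-reach baseline response of a tuning curve
#' @param x a TuningCurve
#' @return scalar (Hz or dF/F), possibly NA
#' @export
curveBaseline <- function(x) x@baseline

#' Per-trial binned means behind a tuning curve
#' @param x a TuningCurve
#' @return trials x bins matrix
#' @export
trialMeans <- function(x) x@trialMeans

#' Range (max minus min) of a tuning curve over defined bins
#' @param x a TuningCurve
#' @return scalar response range
#' @export
curveRange <- function(x) {
  m <- x@mean[is.finite(x@mean)]
  if (!length(m)) return(NA_real_)
  max(m) - min(m)
}

#' ROI masks of a RoiSet
#' @param x a RoiSet
#' @return list of logical matrices
#' @export
roiMasks <- function(x) x@masks

#' Neuropil annulus masks of a RoiSet
#' @param x a RoiSet
#' @return list of logical matrices
#' @export
roiAnnuli <- function(x) x@annuli

setMethod("show", "CouplingParams", function(object) {
  cat(sprintf(
    "CouplingParams: gain=%g, dt=%g s, halfwidth=%g mm, min wall=%g mm, trial=%g cm\n",
    object@gain, object@dt, object@corridorHalfwidth,
    object@minWallDistance, object@trialLength))
})

setMethod("show", "CorridorTrial", function(object) {
  cat(sprintf("CorridorTrial: mode=%s, turn=%g deg", object@mode,
              object@turnAngle))
  if (object@mode == "open_loop")
    cat(sprintf(", hold=%g mm, schedule=%s s", object@openLoopDistance,
                paste(object@schedule, collapse = "/")))
  cat("\n")
})

setMethod("show", "BehaviorTimeSeries", function(object) {
  n <- length(object@t)
  cat(sprintf("BehaviorTimeSeries: %d samples, %d trial(s), %.1f s",
              n, length(unique(object@trialId)),
              if (n) diff(range(object@t)) else 0))
  if (n) cat(sprintf(", wall %0.1f-%0.1f mm",
                     min(object@uRight), max(object@uRight)))
  cat("\n")
})

setMethod("show", "NeuronModel", function(object) {
  cat(sprintf("NeuronModel: %s, baseline %.2g Hz", object@kind,
              object@baseline))
  if (length(object@preferred))
    cat(sprintf(", preferred %s mm", paste(signif(object@preferred, 3),
                                           collapse = ", ")))
  cat(sprintf(", direction gain %.2g, laterality %s\n",
              object@directionGain, object@laterality))
})

setMethod("show", "CalciumMovie", function(object) {
  d <- dim(object@frames)
  cat(sprintf("CalciumMovie: %d x %d px, %d frames", d[1], d[2], d[3]))
  if (d[3] > 1)
    cat(sprintf(" at %.2f Hz", 1 / (object@frameTimes[2] - object@frameTimes[1])))
  if (length(object@groundTruth)) cat(" [synthetic, ground truth attached]")
  cat("\n")
})

setMethod("show", "RoiSet", function(object) {
  cat(sprintf("RoiSet: %d ROI(s)\n", length(object@masks)))
})

setMethod("show", "TuningCurve", function(object) {
  ok <- sum(is.finite(object@mean))
  cat(sprintf(
    "TuningCurve (%s): %d/%d defined bins over %g-%g mm, baseline %.3g\n",
    object@unit, ok, length(object@binCenters),
    min(object@binCenters), max(object@binCenters), object@baseline))
})

setMethod("show", "PixelwiseMap", function(object) {
  cat(sprintf("PixelwiseMap: %d x %d px, median r2 %.3f\n",
              nrow(object@r2), ncol(object@r2),
              stats::median(object@r2, na.rm = TRUE)))
})
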